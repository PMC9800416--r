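#' Pearson chi-square test of independence
#'
#' Pearson's chi-square on an r-by-c contingency table, without continuity
#' correction (the convention that reproduces classic clinical-table
#' p-values on 2-by-2 counts).
#'
#' @param counts A matrix (or data frame of counts) with r, c >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_test(matrix(c(14, 6, 11, 4), nrow = 2))
chi_square_test <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2) abort("contingency table must be at least 2x2")
  if (sum(m) == 0) abort("empty contingency table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero row or column margin: degrees of freedom degenerate")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value when both samples have at most 25 observations and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return One-row tibble: `u` (Mann-Whitney U for `x`), `p_value`,
#'   `exact` (logical path indicator).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # zero-variance degenerate case
  tibble(u = unname(ht$statistic), p_value = min(p, 1), exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment, capped at 1, monotone non-decreasing in p-rank.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and within [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("rho undefined for a constant vector")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Principal component analysis of a samples-by-features table
#'
#' Features are centered and (by default) scaled to unit variance before
#' the decomposition, so scores on differently-scaled markers (such as a
#' seed score and a soil score) are comparable.
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param n_components Number of components to keep.
#' @param scale. Scale features to unit variance first.
#' @return An `hgp_pca` object: list with `scores` (tibble), `loadings`
#'   (matrix), `explained_variance` (proportions, non-increasing).
#' @export
pca_scores <- function(x, n_components = 2, scale. = TRUE) {
  m <- as.matrix(x)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (scale. && any(apply(m, 2, sd) == 0)) {
    abort("cannot scale a zero-variance feature")
  }
  fit <- prcomp(m, center = TRUE, scale. = scale.)
  r <- sum(fit$sdev > max(fit$sdev) * 1e-12)
  if (n_components > r) {
    abort(paste0("n_components (", n_components, ") exceeds rank (", r, ")"))
  }
  keep <- seq_len(n_components)
  structure(list(
    scores = as_tibble(fit$x[, keep, drop = FALSE]),
    loadings = fit$rotation[, keep, drop = FALSE],
    explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[keep],
    centered = fit$center, scaling = fit$scale),
    class = "hgp_pca")
}

#' Agglomerative hierarchical clustering with Euclidean distance
#'
#' @param x Numeric matrix or data frame, one point per row.
#' @param k Number of clusters to cut the tree at.
#' @param linkage `"complete"`, `"ward"` (Ward.D2 on Euclidean distances),
#'   `"average"` or `"single"`.
#' @return List with integer `labels` (cluster per point, in input order),
#'   `merge_heights`, and the `hclust` object.
#' @export
hierarchical_cluster <- function(x, k, linkage = c("complete", "ward",
                                                   "average", "single")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(x)
  if (k < 1 || k > nrow(m)) abort("k must be between 1 and the number of points")
  d <- dist(m, method = "euclidean")
  if (nrow(m) > 1 && max(d) == 0 && k > 1) {
    abort("all points identical: clustering is degenerate")
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(d, method = method)
  list(labels = unname(cutree(hc, k = k)),
       merge_heights = hc$height, hclust = hc)
}
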