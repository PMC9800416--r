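#' Two-group differential expression on TPM
#'
#' Per gene: a two-sided Wilcoxon rank-sum test of group A versus group B
#' on the TPM values (normal approximation with tie and continuity
#' corrections, computed in vectorized form across all genes), a fold
#' change `log2fc = log2((mean TPM_A + 1) / (mean TPM_B + 1))`, and
#' Benjamini-Hochberg adjustment across all tested genes. A gene is called
#' `up_in_A` / `up_in_B` only when both gates pass:
#' `|log2fc| > lfc_threshold` and `fdr < fdr_threshold`; otherwise `ns`.
#' Genes with identical values in every sample get p = 1.
#'
#' @param expr Expression tibble (TPM).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2. By convention group A is the dHGP side.
#' @param lfc_threshold Absolute log2-fold-change gate (1 for tumor
#'   comparisons, 0.5 for the quieter normal-liver comparison).
#' @param fdr_threshold FDR gate (0.05).
#' @param pseudocount Added to both mean TPMs before the ratio.
#' @return An `hgp_de` tibble: `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `direction`; attributes record the thresholds and group sizes.
#' @export
run_de <- function(expr, group_a, group_b,
                   lfc_threshold = 1, fdr_threshold = 0.05,
                   pseudocount = 1) {
  m <- expr_matrix(expr)
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("samples absent from expression table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  p <- rowwise_wilcoxon_auto(a, b)
  log2fc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  fdr <- bh_adjust(p)
  direction <- dplyr::case_when(
    fdr < fdr_threshold & log2fc > lfc_threshold ~ "up_in_A",
    fdr < fdr_threshold & log2fc < -lfc_threshold ~ "up_in_B",
    TRUE ~ "ns")
  out <- tibble(gene_id = rownames(m), log2fc = unname(log2fc),
                p_value = unname(p), fdr = unname(fdr),
                direction = direction)
  structure(out, class = c("hgp_de", class(out)),
            lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
            n_a = ncol(a), n_b = ncol(b))
}

# Row-wise two-sided Wilcoxon rank-sum p-values with the same path switch
# as the scalar primitive: the exact null distribution when both groups
# have <= 25 samples and the row is tie-free, otherwise the normal
# approximation with tie and continuity corrections (matching
# wilcox.test(exact = FALSE, correct = TRUE)). Zero-variance rows get
# p = 1.
rowwise_wilcoxon_auto <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ru <- rowwise_rank_stats(a, b)
  p <- rowwise_approx_p(ru, na, nb)
  if (na <= 25 && nb <= 25) {
    tiefree <- ru$tie_term == 0
    if (any(tiefree)) {
      u <- ru$u[tiefree]
      upper <- u > na * nb / 2
      pe <- ifelse(upper,
                   stats::pwilcox(u - 1, na, nb, lower.tail = FALSE),
                   stats::pwilcox(u, na, nb))
      p[tiefree] <- pmin(2 * pe, 1)
    }
  }
  p
}

rowwise_rank_stats <- function(a, b) {
  x <- cbind(a, b)
  na <- ncol(a)
  ranks <- t(apply(x, 1, rank))
  u <- rowSums(ranks[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  tie_term <- apply(x, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
  list(u = u, tie_term = tie_term)
}

rowwise_approx_p <- function(ru, na, nb) {
  n <- na + nb
  sigma2 <- (na * nb / 12) * ((n + 1) - ru$tie_term / (n * (n - 1)))
  z <- ru$u - na * nb / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 1  # all values tied: no evidence either way
  pmin(p, 1)
}

# Approximation-only variant (kept for large or tie-heavy designs).
rowwise_wilcoxon_p <- function(a, b) {
  rowwise_approx_p(rowwise_rank_stats(a, b), ncol(a), ncol(b))
}

#' Intersect up-regulated DEG sets from two comparisons
#'
#' Builds the shared seed signatures: genes significant with the same
#' direction in both the primary-lesion and the liver-metastasis
#' comparison (both run with the dHGP subgroup as group A). `up_in_A`
#' yields the shared dHGP-up set, `up_in_B` the shared rHGP-up set.
#'
#' @param de_primary,de_mets `hgp_de` results with matching orientation.
#' @param direction `"up_in_A"` or `"up_in_B"`.
#' @param name Gene-set name; defaults to `"dHGP_shared"` / `"rHGP_shared"`.
#' @return A one-row gene-set tibble (`set`, `description`, `genes`); the
#'   set may be empty, which is reported with a message, not an error.
#' @export
intersect_up_sets <- function(de_primary, de_mets,
                              direction = c("up_in_A", "up_in_B"),
                              name = NULL) {
  direction <- match.arg(direction)
  name <- name %||% if (direction == "up_in_A") "dHGP_shared" else "rHGP_shared"
  g1 <- de_primary$gene_id[de_primary$direction == direction]
  g2 <- de_mets$gene_id[de_mets$direction == direction]
  shared <- intersect(g1, g2)
  if (length(shared) == 0) {
    inform(paste0("intersection for ", name, " is empty"))
  }
  tibble(set = name, description = paste0("shared ", direction, " genes"),
         genes = list(shared))
}
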