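#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a positive outranks a negative,
#' with 0.5 credit for ties; the 95% CI uses the DeLong variance. Higher
#' scores are always treated as more positive (the direction is fixed, so a
#' score with no signal gives AUC near 0.5 rather than being flipped).
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or coercible) class labels; `TRUE` = positive.
#' @return An `hgp_roc` object: tibble of `threshold`, `tpr`, `fpr` rows
#'   with attributes `auc` and `ci95`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(labels))) abort("missing values not allowed")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  r <- pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  # Mann-Whitney form from midranks: exact pair counting incl. tie credit
  rk <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(auc, auc))
  if (any(!is.finite(ci))) ci <- c(auc, auc)
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  curve <- tibble(threshold = r$thresholds,
                  tpr = r$sensitivities,
                  fpr = 1 - r$specificities) |>
    arrange(.data$fpr, .data$tpr)
  structure(curve, class = c("hgp_roc", class(curve)),
            auc = auc, ci95 = ci, n_pos = n_pos, n_neg = n_neg)
}

#' @export
print.hgp_roc <- function(x, ...) {
  ci <- attr(x, "ci95")
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              attr(x, "auc"), ci[1], ci[2], attr(x, "n_pos"), attr(x, "n_neg")))
  invisible(x)
}

#' Combine two markers into one score
#'
#' Fits an in-sample logistic regression of the class labels on both
#' markers (iteratively reweighted least squares, tolerance 1e-8, up to 100
#' iterations) and returns the linear predictor as the combined marker.
#' Under perfect separation the likelihood diverges; the combination then
#' falls back to the sum of the per-marker rank-standardized values, with a
#' message.
#'
#' @param m1,m2 Numeric marker vectors.
#' @param labels Logical class labels.
#' @return Numeric combined score with attribute `method` (`"logistic"` or
#'   `"rank_sum"`).
#' @export
combine_markers <- function(m1, m2, labels) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (length(m1) != n || length(m2) != n) abort("marker lengths must match labels")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(labels ~ m1 + m2, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    inform("perfect separation in logistic combination; using rank-sum fallback")
    combined <- rank(m1) / n + rank(m2) / n
    return(structure(combined, method = "rank_sum"))
  }
  structure(unname(predict(fit, type = "link")), method = "logistic")
}
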