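#' Volcano plot of a differential-expression result
#'
#' @param object An `hgp_de` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hgp_de <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up_in_A = "#c0392b",
                                            up_in_B = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_threshold"),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change (A / B)", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Seed-soil score scatter per patient
#'
#' C-score against Ln-score, colored by HGP, with the median split lines
#' used for quadrant classification.
#'
#' @param object An `hgp_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hgp_scores <- function(object, ...) {
  sc <- as_tibble(object)[complete.cases(object[c("c_score", "ln_score")]), ]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$c_score, y = .data$ln_score,
                                   colour = .data$hgp)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = median(sc$c_score),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = median(sc$ln_score),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "C-score (seed)", y = "Ln-score (soil)", colour = "HGP") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object An `hgp_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hgp_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object An `hgp_km` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hgp_km <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Relapse-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
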