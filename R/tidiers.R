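#' Tidiers for seedsoil result objects
#'
#' Broom-style `tidy()` / `glance()` methods: `tidy()` returns the per-unit
#' table (genes, curve points, model terms), `glance()` a one-row summary.
#'
#' @param x A seedsoil result object.
#' @param ... Unused.
#' @return A tibble.
#' @name seedsoil-tidiers
NULL

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_de <- function(x, ...) as_tibble(x)

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_de <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up_in_a = sum(x$direction == "up_in_A"),
         n_up_in_b = sum(x$direction == "up_in_B"),
         lfc_threshold = attr(x, "lfc_threshold"),
         fdr_threshold = attr(x, "fdr_threshold"),
         n_a = attr(x, "n_a"), n_b = attr(x, "n_b"))
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_roc <- function(x, ...) as_tibble(x)

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_roc <- function(x, ...) {
  ci <- attr(x, "ci95")
  tibble(auc = attr(x, "auc"), ci_low = ci[1], ci_high = ci[2],
         n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_roc_set <- function(x, ...) as_tibble(x)

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_roc_set <- function(x, ...) {
  best <- x$marker[which.max(x$auc)]
  tibble(best_marker = best, best_auc = max(x$auc),
         combination = attr(x, "combination"))
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_cox <- function(x, ...) {
  tibble(term = x$term, estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p_value,
         conf.low = log(x$ci_low), conf.high = log(x$ci_high))
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_cox <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, hr = x$hr,
         hr_ci_low = x$ci_low, hr_ci_high = x$ci_high)
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_km <- function(x, ...) as_tibble(x)

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_km <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$group) |>
    summarise(n = max(.data$n_risk, na.rm = TRUE),
              n_event = sum(.data$n_event),
              final_survival = min(.data$survival), .groups = "drop")
}

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::tidy
tidy.hgp_pca <- function(x, ...) x$scores

#' @rdname seedsoil-tidiers
#' @exportS3Method generics::glance
glance.hgp_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance),
         explained_variance = x$explained_variance)
}
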