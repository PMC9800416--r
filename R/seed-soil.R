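#' Median split into high and low groups
#'
#' Values strictly above the median are `"high"`; values at or below the
#' median (including ties at the median) are `"low"`. The tie rule is
#' deterministic and conservative toward the high (dHGP-like) call.
#'
#' @param values Numeric vector, length >= 2.
#' @return Character vector of `"high"` / `"low"` in input order.
#' @export
median_split <- function(values) {
  if (length(values) < 2) abort("need at least 2 values")
  if (any(is.na(values))) abort("missing values not allowed")
  ifelse(values > median(values), "high", "low")
}

#' Seed-soil quadrant classification of patients
#'
#' Dichotomizes the C-score (seed) and Ln-score (soil) at their medians
#' and assigns each patient a quadrant: `HH` (both high), `HL` (C high
#' only), `LH` (Ln high only), `LL` (both low). Association with the HGP
#' label is tested by Pearson chi-square on the concordant/discordant
#' grouping (`HH` vs intermediate `HL`+`LH` vs `LL`), dropping empty rows.
#'
#' Note: in the motivating cohort the concordant quadrants were almost
#' pure (all concordant-high patients desmoplastic, 11/12 concordant-low
#' replacement); such counts are data-dependent and are not reproduced by
#' the simulator.
#'
#' @param scores An `hgp_scores` tibble with complete `c_score`,
#'   `ln_score` and `hgp` per patient.
#' @return List: `assignments` (patient, levels, quadrant, HGP),
#'   `counts` (grouping-by-HGP table) and `test` (chi-square tibble, `NA`
#'   p-value if the table degenerates).
#' @export
quadrant_classify <- function(scores) {
  sc <- score_rows(scores)
  assignments <- sc |>
    mutate(c_level = median_split(.data$c_score),
           ln_level = median_split(.data$ln_score),
           quadrant = paste0(toupper(substr(.data$c_level, 1, 1)),
                             toupper(substr(.data$ln_level, 1, 1))),
           grouping = case_when(.data$quadrant == "HH" ~ "concordant_high",
                                .data$quadrant == "LL" ~ "concordant_low",
                                TRUE ~ "intermediate")) |>
    select("patient_id", "c_level", "ln_level", "quadrant", "grouping", "hgp")
  counts <- table(assignments$grouping, assignments$hgp)
  test_tab <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  test <- if (nrow(test_tab) >= 2 && ncol(test_tab) >= 2) {
    chi_square_test(test_tab)
  } else {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  list(assignments = assignments, counts = counts, test = test)
}

# Complete-case score rows with an informative message on drops.
score_rows <- function(scores) {
  need <- c("patient_id", "hgp", "c_score", "ln_score")
  stopifnot(all(need %in% names(scores)))
  ok <- complete.cases(scores[c("c_score", "ln_score")])
  if (any(!ok)) {
    inform(paste0("dropping ", sum(!ok), " patient(s) with missing scores"))
  }
  as_tibble(scores)[ok, ]
}

#' Hierarchical clustering of patients on the two scores
#'
#' Clusters patients on their (C-score, Ln-score) pairs with Euclidean
#' distance and complete linkage, after z-scoring each score (the two
#' statistics live on different scales); standardization can be disabled.
#'
#' @param scores An `hgp_scores` tibble.
#' @param k Number of clusters.
#' @param standardize Z-score each column first.
#' @param linkage Linkage passed to [hierarchical_cluster()].
#' @return Tibble: `patient_id`, `hgp`, `cluster`.
#' @export
cluster_patients <- function(scores, k = 2, standardize = TRUE,
                             linkage = "complete") {
  sc <- score_rows(scores)
  m <- as.matrix(sc[c("c_score", "ln_score")])
  if (standardize) m <- scale(m)
  cl <- hierarchical_cluster(m, k = k, linkage = linkage)
  tibble(patient_id = sc$patient_id, hgp = sc$hgp, cluster = cl$labels)
}

#' Predictive accuracy of the seed and soil scores for HGP type
#'
#' ROC analysis of the C-score, the Ln-score and their logistic
#' combination ([combine_markers()]) against the dHGP-vs-rHGP label.
#' Deterministic given the inputs.
#'
#' @param scores An `hgp_scores` tibble; patients with `hgp` other than
#'   dHGP/rHGP are dropped.
#' @return An `hgp_roc_set`: tibble with one row per marker (`marker`,
#'   `auc`, `ci_low`, `ci_high`) carrying the full `hgp_roc` objects in
#'   the `roc` attribute.
#' @export
evaluate_predictors <- function(scores) {
  sc <- score_rows(scores) |> filter(.data$hgp %in% c("dHGP", "rHGP"))
  if (length(unique(sc$hgp)) < 2) abort("need both dHGP and rHGP patients")
  labels <- sc$hgp == "dHGP"
  combined <- combine_markers(sc$c_score, sc$ln_score, labels)
  rocs <- list(c_score = roc_auc(sc$c_score, labels),
               ln_score = roc_auc(sc$ln_score, labels),
               combined = roc_auc(as.numeric(combined), labels))
  out <- bind_rows(imap(rocs, function(r, nm) {
    ci <- attr(r, "ci95")
    tibble(marker = nm, auc = attr(r, "auc"), ci_low = ci[1], ci_high = ci[2])
  }))
  structure(out, class = c("hgp_roc_set", class(out)), roc = rocs,
            combination = attr(combined, "method"))
}
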