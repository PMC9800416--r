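#' Single-sample gene-set enrichment score (running-sum integral)
#'
#' Genes are sorted by decreasing expression within the sample (ties broken
#' lexicographically by gene id). Position `i` carries rank weight
#' `(N - i + 1)^alpha` if the gene belongs to the set. With `P_in(i)` the
#' weighted fraction of set genes at or above position `i` and `P_out(i)`
#' the plain fraction of non-set genes, the enrichment score is the full
#' running-sum integral `ES = sum_i (P_in(i) - P_out(i))` (not the maximum
#' deviation). Because weights are rank-based, ES depends only on the
#' expression ranks within the sample.
#'
#' @param values Named numeric vector of expression values (gene -> TPM).
#' @param genes Character vector of set members, or a one-row gene-set
#'   tibble.
#' @param alpha Rank-weight exponent (0.25, the conventional choice).
#' @return The enrichment score (a single number).
#' @export
ssgsea_es <- function(values, genes, alpha = 0.25) {
  genes <- set_members(genes)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort("values must be named by unique gene ids")
  }
  n <- length(values)
  if (n < 2) abort("need at least 2 measured genes")
  in_set <- names(values) %in% genes
  n_in <- sum(in_set)
  if (n_in == 0) abort("gene set has no overlap with measured genes")
  if (n_in == n) abort("gene set covers every measured gene; ES undefined")
  ord <- order(-values, names(values))
  in_ord <- in_set[ord]
  w <- (n - seq_len(n) + 1)^alpha
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out)
}

set_members <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot("genes" %in% names(genes), nrow(genes) == 1)
    genes <- genes$genes[[1]]
  }
  unique(as.character(genes))
}

#' Score a collection of gene sets across all samples
#'
#' Computes [ssgsea_es()] per (set, sample). With `normalize = TRUE` every
#' score is divided by the range (max - min) of the raw scores taken
#' jointly over all sets and samples, the original ssGSEA normalization;
#' a zero range leaves raw scores with a warning.
#'
#' @param expr Expression tibble.
#' @param sets Gene-set tibble ([read_gmt()]) or named list of gene
#'   vectors.
#' @param alpha Rank-weight exponent.
#' @param normalize Apply cohort-joint min-max range division.
#' @return A signature tibble: `set` column plus one numeric column per
#'   sample.
#' @export
score_signatures <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  m <- expr_matrix(expr)
  set_list <- gene_set_list(sets)
  if (length(set_list) == 0) abort("no gene sets supplied")
  n <- nrow(m)
  membership <- map(set_list, ~ rownames(m) %in% .x)
  es <- matrix(NA_real_, length(set_list), ncol(m),
               dimnames = list(names(set_list), colnames(m)))
  w_rank <- (n - seq_len(n) + 1)^alpha
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], rownames(m))
    for (s in seq_along(set_list)) {
      in_ord <- membership[[s]][ord]
      n_in <- sum(in_ord)
      if (n_in == 0) abort(paste0("set ", names(set_list)[s],
                                  " has no overlap with measured genes"))
      if (n_in == n) abort(paste0("set ", names(set_list)[s],
                                  " covers every measured gene"))
      w <- w_rank
      w[!in_ord] <- 0
      es[s, j] <- sum(cumsum(w) / sum(w) - cumsum(!in_ord) / (n - n_in))
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng == 0) {
      warn("score range is zero; returning raw scores")
    } else {
      es <- es / rng
    }
  }
  dplyr::bind_cols(tibble(set = rownames(es)), as_tibble(es))
}

#' Seed and soil scores per patient
#'
#' The dHGP and rHGP scores are ssGSEA scores of the shared dHGP-up and
#' rHGP-up signatures on each patient's primary-lesion (C) sample, scored
#' and normalized jointly; the seed statistic is their difference,
#' `c_score = dhgp_score - rhgp_score`. The soil statistic `ln_score` is
#' the ssGSEA score of the normal-liver fibrosis panel on the patient's Ln
#' sample. Patients missing a C or Ln sample get `NA` in the affected
#' fields, with a message.
#'
#' @param expr_c Expression tibble of primary-lesion samples.
#' @param expr_ln Expression tibble of normal-liver samples.
#' @param ann Sample annotation tibble covering both.
#' @param dhgp_set,rhgp_set,ln_set Gene sets (character vectors or one-row
#'   gene-set tibbles).
#' @param alpha Rank-weight exponent.
#' @param normalize Cohort-joint range normalization before differencing.
#' @return An `hgp_scores` tibble: `patient_id`, `hgp`, `dhgp_score`,
#'   `rhgp_score`, `c_score`, `ln_score`.
#' @export
compute_scores <- function(expr_c, expr_ln, ann, dhgp_set, rhgp_set, ln_set,
                           alpha = 0.25, normalize = TRUE) {
  ann <- validate_annotation(ann)
  seed_sets <- tibble(set = c("dHGP", "rHGP"),
                      description = c("shared dHGP-up", "shared rHGP-up"),
                      genes = list(set_members(dhgp_set), set_members(rhgp_set)))
  sc <- score_signatures(expr_c, seed_sets, alpha = alpha, normalize = normalize)
  sl <- score_signatures(expr_ln,
                         tibble(set = "Ln", description = "normal-liver panel",
                                genes = list(set_members(ln_set))),
                         alpha = alpha, normalize = normalize)
  c_of <- setNames(ann$sample_id[ann$tissue == "C"],
                   ann$patient_id[ann$tissue == "C"])
  ln_of <- setNames(ann$sample_id[ann$tissue == "Ln"],
                    ann$patient_id[ann$tissue == "Ln"])
  patients <- ann |> distinct(.data$patient_id, .data$hgp)
  sc_m <- expr_matrix(rename(sc, gene_id = "set"), .validate = FALSE)
  sl_m <- expr_matrix(rename(sl, gene_id = "set"), .validate = FALSE)
  get_score <- function(mat, row, sample_id) {
    if (is.na(sample_id) || !sample_id %in% colnames(mat)) NA_real_
    else mat[row, sample_id]
  }
  out <- patients |>
    mutate(
      dhgp_score = map_dbl(.data$patient_id,
                           ~ get_score(sc_m, "dHGP", c_of[.x] %||% NA)),
      rhgp_score = map_dbl(.data$patient_id,
                           ~ get_score(sc_m, "rHGP", c_of[.x] %||% NA)),
      ln_score = map_dbl(.data$patient_id,
                         ~ get_score(sl_m, "Ln", ln_of[.x] %||% NA)),
      c_score = .data$dhgp_score - .data$rhgp_score)
  n_miss <- sum(is.na(out$c_score) | is.na(out$ln_score))
  if (n_miss > 0) {
    inform(paste0(n_miss, " patient(s) missing a C or Ln sample; fields set to NA"))
  }
  out <- out[c("patient_id", "hgp", "dhgp_score", "rhgp_score",
               "c_score", "ln_score")]
  structure(out, class = c("hgp_scores", class(out)))
}
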