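#' Unsupervised immune/stromal transcriptome subtyping of metastases
#'
#' Clusters metastatic lesions on their signature-score profiles
#' (signatures z-scored across lesions; Euclidean distance, Ward linkage)
#' and cuts the tree at `k`. Clusters are ranked by their mean combined
#' immune + stromal signature score and labeled `High_IS`, `Medium_IS`,
#' `Low_IS` (for `k = 3`; other `k` get rank labels `IS_rank1` highest to
#' `IS_rank<k>` lowest). The labeling is invariant to cluster index
#' permutation by construction.
#'
#' @param signatures Signature tibble from [score_signatures()] (`set`
#'   column plus one column per lesion).
#' @param immune_sets,stromal_sets Names of the immune and stromal
#'   signature rows used for ranking.
#' @param k Number of subtypes (3 reproduces the High/Medium/Low scheme).
#' @return Tibble: `sample_id`, `subtype` (ordered factor, highest first).
#' @export
assign_subtypes <- function(signatures, immune_sets, stromal_sets, k = 3) {
  stopifnot("set" %in% names(signatures))
  m <- expr_matrix(rename(signatures, gene_id = "set"), .validate = FALSE)
  missing <- setdiff(c(immune_sets, stromal_sets), rownames(m))
  if (length(missing) > 0) {
    abort(paste0("signature rows not found: ", paste(missing, collapse = ", ")))
  }
  if (ncol(m) < k) abort("fewer lesions than clusters requested")
  z <- t(scale(t(m)))          # z-score each signature across lesions
  z[!is.finite(z)] <- 0        # constant signatures carry no contrast
  cl <- hierarchical_cluster(t(z), k = k, linkage = "ward")
  is_score <- colMeans(z[unique(c(immune_sets, stromal_sets)), , drop = FALSE])
  cluster_rank <- rank(-vapply(seq_len(k), function(g) {
    mean(is_score[cl$labels == g])
  }, numeric(1)), ties.method = "first")
  labels <- if (k == 3) c("High_IS", "Medium_IS", "Low_IS") else
    paste0("IS_rank", seq_len(k))
  subtype <- labels[cluster_rank[cl$labels]]
  tibble(sample_id = colnames(m),
         subtype = factor(subtype, levels = labels))
}

#' Patient-level Medium-IS flag from lesion subtypes
#'
#' The risk score needs a per-patient subtype point while subtyping is
#' per lesion. `any_medium` (default) flags a patient when any lesion is
#' `Medium_IS`; `majority` takes the modal lesion subtype with ties broken
#' toward `Medium_IS`.
#'
#' @param assignments Lesion subtype tibble from [assign_subtypes()].
#' @param ann Sample annotation tibble.
#' @param rule `"any_medium"` or `"majority"`.
#' @return Tibble: `patient_id`, `medium_flag` (logical).
#' @export
patient_subtype <- function(assignments, ann, rule = c("any_medium", "majority")) {
  rule <- match.arg(rule)
  ann <- validate_annotation(ann)
  l_ann <- ann |> filter(.data$tissue == "L")
  unassigned <- setdiff(l_ann$sample_id, assignments$sample_id)
  if (length(unassigned) > 0) {
    abort(paste0("unassigned L samples: ", paste(head(unassigned, 5),
                                                 collapse = ", ")))
  }
  joined <- inner_join(l_ann, assignments, by = "sample_id")
  no_lesion <- setdiff(unique(ann$patient_id), joined$patient_id)
  if (length(no_lesion) > 0) {
    abort(paste0("patient(s) without L samples: ",
                 paste(head(no_lesion, 5), collapse = ", ")))
  }
  joined |>
    group_by(.data$patient_id) |>
    summarise(medium_flag = if (rule == "any_medium") {
      any(.data$subtype == "Medium_IS")
    } else {
      tab <- table(.data$subtype)
      top <- names(tab)[tab == max(tab)]
      "Medium_IS" %in% top && tab["Medium_IS"] == max(tab)
    }, .groups = "drop")
}

#' Composite HGP + transcriptome-subtype risk score
#'
#' Non-dHGP status scores 1 point and a Medium-IS transcriptome subtype
#' scores 1 point; dHGP status and a non-Medium subtype score 0. Patients
#' with 0-1 total points are low risk; 2 points is high risk. Impure-HGP
#' patients count as non-dHGP.
#'
#' @param hgp Character vector: `"dHGP"`, `"rHGP"`, `"impure"` or
#'   `"non_dHGP"`.
#' @param medium_flag Logical vector: patient carries a Medium-IS lesion.
#' @return Tibble: `hgp_point`, `subtype_point`, `total`, `risk_group`.
#' @export
risk_score <- function(hgp, medium_flag) {
  known <- c("dHGP", "rHGP", "impure", "non_dHGP")
  bad <- setdiff(unique(hgp), known)
  if (length(bad) > 0) {
    abort(paste0("unknown HGP status: ", paste(bad, collapse = ", ")))
  }
  if (length(hgp) != length(medium_flag)) abort("inputs differ in length")
  if (any(is.na(hgp)) || any(is.na(medium_flag))) abort("missing inputs")
  hgp_point <- as.integer(hgp != "dHGP")
  subtype_point <- as.integer(medium_flag)
  total <- hgp_point + subtype_point
  tibble(hgp_point = hgp_point, subtype_point = subtype_point,
         total = total,
         risk_group = ifelse(total == 2, "high", "low"))
}
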