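#' Pipeline configuration
#'
#' All analysis thresholds in one place. Defaults follow the study
#' conventions: |log2FC| > 1 with FDR < 0.05 for the metastasis (L) and
#' primary (C) comparisons, the softer |log2FC| > 0.5 gate for the quiet
#' normal-liver (Ln) comparison, ssGSEA exponent 0.25 with cohort-joint
#' normalization, complete linkage for the two-score patient clustering,
#' Ward linkage with k = 3 for lesion subtyping, the any-Medium patient
#' rule, and a 6-month survival horizon.
#'
#' @param de_l,de_c,de_ln Lists with `lfc` and `fdr` gates per comparison.
#' @param alpha ssGSEA rank-weight exponent.
#' @param normalize_scores Cohort-joint range normalization of ssGSEA.
#' @param patient_linkage Linkage for the C/Ln-score patient clustering.
#' @param subtype_k,subtype_linkage Lesion subtyping parameters.
#' @param immune_sets,stromal_sets Signature names ranking the subtypes.
#' @param patient_rule Lesion-to-patient subtype rule.
#' @param horizon Early-relapse horizon in months.
#' @param min_signature_size When a derived signature is empty under the
#'   configured gates, the pipeline falls back to this many top-ranked
#'   direction-concordant genes (with a warning) so scoring can proceed.
#' @param seed RNG seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(de_l = list(lfc = 1, fdr = 0.05),
                            de_c = list(lfc = 1, fdr = 0.05),
                            de_ln = list(lfc = 0.5, fdr = 0.05),
                            alpha = 0.25,
                            normalize_scores = TRUE,
                            patient_linkage = "complete",
                            subtype_k = 3, subtype_linkage = "ward",
                            immune_sets = "immune",
                            stromal_sets = "emt_angio",
                            patient_rule = "any_medium",
                            horizon = 6,
                            min_signature_size = 9,
                            seed = 1L) {
  cfg <- list(de_l = de_l, de_c = de_c, de_ln = de_ln, alpha = alpha,
              normalize_scores = normalize_scores,
              patient_linkage = patient_linkage,
              subtype_k = subtype_k, subtype_linkage = subtype_linkage,
              immune_sets = immune_sets, stromal_sets = stromal_sets,
              patient_rule = patient_rule, horizon = horizon,
              min_signature_size = min_signature_size,
              seed = as.integer(seed))
  stopifnot(cfg$de_l$lfc > 0, cfg$de_c$lfc > 0, cfg$de_ln$lfc > 0,
            cfg$de_l$fdr > 0, cfg$de_c$fdr > 0, cfg$de_ln$fdr > 0)
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full seed-and-soil analysis
#'
#' Executes, in order: differential expression on the L, C and Ln
#' comparisons (dHGP as group A); construction of the shared dHGP-up /
#' rHGP-up seed signatures and the normal-liver panel; ssGSEA scoring to
#' C-scores and Ln-scores; seed-soil quadrant classification, clustering
#' and ROC evaluation; lesion transcriptome subtyping and the composite
#' risk score; and survival analysis of the early-relapse endpoint for
#' both the HGP and risk grouping. All artifacts are written under
#' `outdir` along with a run log.
#'
#' @param cohort An `hgp_cohort` list (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param outdir Output directory for artifacts.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of every stage result.
#' @export
run_pipeline <- function(cohort, outdir, config = pipeline_config()) {
  stopifnot(inherits(cohort, "hgp_cohort"), inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    inform(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cfg_hash <- substr(rlang::hash(unclass(config)), 1, 12)
  cat("", file = log_path)
  log_line("seedsoil ", as.character(utils::packageVersion("seedsoil")),
           " | config hash ", cfg_hash, " | seed ", config$seed)

  expr <- cohort$expression
  ann <- validate_annotation(cohort$annotation)
  clinical <- validate_clinical(cohort$clinical)

  groups <- function(tissue, hgp) {
    ann$sample_id[ann$tissue == tissue & ann$hgp == hgp]
  }
  de <- run_stage("differential expression", {
    for (h in c("dHGP", "rHGP")) {
      if (sum(ann$hgp == h) == 0) {
        stop("no ", h, " samples in the cohort", call. = FALSE)
      }
    }
    list(
      L = run_de(align_cohort(expr, ann, "L"), groups("L", "dHGP"),
                 groups("L", "rHGP"), config$de_l$lfc, config$de_l$fdr),
      C = run_de(align_cohort(expr, ann, "C"), groups("C", "dHGP"),
                 groups("C", "rHGP"), config$de_c$lfc, config$de_c$fdr),
      Ln = run_de(align_cohort(expr, ann, "Ln"), groups("Ln", "dHGP"),
                  groups("Ln", "rHGP"), config$de_ln$lfc, config$de_ln$fdr))
  })
  log_line("DE: L ", sum(de$L$direction != "ns"), " | C ",
           sum(de$C$direction != "ns"), " | Ln ",
           sum(de$Ln$direction != "ns"), " significant genes")

  signatures <- run_stage("signature construction", {
    # when the dual gates leave a signature empty, degrade gracefully to
    # the top-ranked direction-concordant genes so scoring can proceed;
    # the DE tables still report the honest (empty) calls
    k <- config$min_signature_size
    with_fallback <- function(gated, ranked, name) {
      if (length(gated) > 0) return(gated)
      warn(paste0("signature '", name, "' empty under the configured ",
                  "gates; falling back to the top ", k,
                  " concordant genes by p-value"))
      head(ranked, k)
    }
    concordant <- function(sign) {
      both <- inner_join(as_tibble(de$C), as_tibble(de$L), by = "gene_id",
                         suffix = c("_c", "_l"))
      both <- both[sign * both$log2fc_c > 0 & sign * both$log2fc_l > 0, ]
      both$gene_id[order(pmax(both$p_value_c, both$p_value_l))]
    }
    dhgp <- intersect_up_sets(de$C, de$L, "up_in_A")
    rhgp <- intersect_up_sets(de$C, de$L, "up_in_B")
    dhgp$genes[[1]] <- with_fallback(dhgp$genes[[1]], concordant(1), "dHGP_shared")
    rhgp$genes[[1]] <- with_fallback(rhgp$genes[[1]], concordant(-1), "rHGP_shared")
    ln_up <- de$Ln$gene_id[de$Ln$direction == "up_in_A"]
    ln_ranked <- with(de$Ln, gene_id[log2fc > 0][order(p_value[log2fc > 0])])
    ln <- tibble(set = "Ln_panel",
                 description = "normal-liver dHGP-up genes",
                 genes = list(with_fallback(ln_up, ln_ranked, "Ln_panel")))
    out <- bind_rows(dhgp, rhgp, ln)
    if (any(lengths(out$genes) == 0)) {
      stop("signature construction found no usable genes", call. = FALSE)
    }
    out
  })
  log_line("signatures: ",
           paste(signatures$set, lengths(signatures$genes),
                 sep = "=", collapse = " | "))

  scores <- run_stage("scoring", {
    compute_scores(align_cohort(expr, ann, "C"), align_cohort(expr, ann, "Ln"),
                   ann,
                   dhgp_set = signatures$genes[[1]],
                   rhgp_set = signatures$genes[[2]],
                   ln_set = signatures$genes[[3]],
                   alpha = config$alpha, normalize = config$normalize_scores)
  })

  seed_soil <- run_stage("seed-soil classification", {
    list(quadrants = quadrant_classify(scores),
         clusters = cluster_patients(scores, k = 2,
                                     linkage = config$patient_linkage),
         rocs = evaluate_predictors(scores))
  })
  log_line("seed-soil: quadrant p ",
           signif(seed_soil$quadrants$test$p_value, 3), " | combined AUC ",
           signif(seed_soil$rocs$auc[seed_soil$rocs$marker == "combined"], 3))

  subtype <- run_stage("transcriptome subtyping", {
    sig_sets <- cohort$modules %||%
      stop("cohort carries no signature gene sets for subtyping", call. = FALSE)
    lesion_sig <- score_signatures(align_cohort(expr, ann, "L"), sig_sets,
                                   alpha = config$alpha)
    assignments <- assign_subtypes(lesion_sig,
                                   immune_sets = config$immune_sets,
                                   stromal_sets = config$stromal_sets,
                                   k = config$subtype_k)
    flags <- patient_subtype(assignments, ann, rule = config$patient_rule)
    list(signatures = lesion_sig, assignments = assignments, flags = flags)
  })

  risk <- run_stage("risk scoring", {
    pts <- ann |> distinct(.data$patient_id, .data$hgp) |>
      inner_join(subtype$flags, by = "patient_id") |>
      mutate(hgp_status = ifelse(.data$hgp == "dHGP", "dHGP", "non_dHGP"))
    dplyr::bind_cols(pts["patient_id"], pts["hgp_status"],
                     risk_score(pts$hgp_status, pts$medium_flag))
  })
  log_line("risk: ", sum(risk$risk_group == "high"), " high / ",
           sum(risk$risk_group == "low"), " low")

  surv <- run_stage("survival analysis", {
    base <- clinical |>
      inner_join(risk, by = "patient_id") |>
      mutate(time = .data$rfs_time_months, event = .data$rfs_event)
    by_hgp <- mutate(base, group = .data$hgp_status)
    by_risk <- mutate(base, group = .data$risk_group)
    analyse <- function(s) {
      s6 <- censor_at(s, config$horizon)
      two_groups <- length(unique(s6$group)) == 2
      list(km = km_curve(s6),
           log_rank = if (two_groups && sum(s6$event) > 0) log_rank(s6)
                      else NULL,
           cox = if (two_groups) {
             tryCatch(cox_univariate(s6), error = function(e) NULL)
           },
           rfs6m = rfs6m(s, horizon = config$horizon))
    }
    list(hgp = analyse(by_hgp), risk = analyse(by_risk))
  })

  results <- list(de = de, signatures = signatures, scores = scores,
                  seed_soil = seed_soil, subtype = subtype, risk = risk,
                  survival = surv, config = config)
  run_stage("artifact output", write_artifacts(results, outdir))
  log_line("done: ", length(list.files(outdir)), " artifacts in ", outdir)
  invisible(results)
}

write_artifacts <- function(results, outdir) {
  p <- function(...) file.path(outdir, ...)
  readr::write_tsv(as_tibble(results$de$L), p("de_L.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(results$de$C), p("de_C.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(results$de$Ln), p("de_Ln.tsv"), progress = FALSE)
  write_gmt(results$signatures, p("signatures.gmt"))
  readr::write_tsv(as_tibble(results$scores), p("scores.tsv"), progress = FALSE)
  readr::write_tsv(results$seed_soil$quadrants$assignments,
                   p("quadrants.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(markers = as_tibble(results$seed_soil$rocs),
         quadrant_test = results$seed_soil$quadrants$test),
    p("roc.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_tsv(results$subtype$assignments, p("subtypes.tsv"),
                   progress = FALSE)
  readr::write_tsv(results$risk, p("risk.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(results$survival$hgp$km), p("km_hgp.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(results$survival$risk$km), p("km_risk.tsv"),
                   progress = FALSE)
  surv_summary <- map(results$survival, function(s) {
    list(log_rank = s$log_rank,
         cox = if (!is.null(s$cox)) glance(s$cox) else NULL,
         early_relapse = as.data.frame(s$rfs6m$table),
         early_relapse_test = s$rfs6m$test)
  })
  jsonlite::write_json(surv_summary, p("survival_tests.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [simulate_cohort()] + [write_cohort()] used by the
#' command-line interface; logs the seed and design.
#'
#' @param outdir Output directory.
#' @param design A [cohort_design()].
#' @param seed RNG seed (defaults to the design's).
#' @return Named vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(outdir, design = cohort_design(),
                              seed = design$seed) {
  inform(paste0("simulating cohort: ", design$n_dhgp, " dHGP + ",
                design$n_rhgp, " rHGP patients, ", design$n_genes,
                " genes, seed ", seed))
  write_cohort(simulate_cohort(design, seed = seed), outdir)
}
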