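#' Design of a synthetic seed-and-soil cohort
#'
#' Describes a simulated cohort of colorectal-liver-metastasis patients
#' with matched primary (C), metastasis (L) and normal-liver (Ln) samples
#' and planted expression modules mirroring the programs that separate
#' desmoplastic (dHGP) from replacement (rHGP) growth patterns:
#' EMT/angiogenesis/stroma up in dHGP primaries and metastases, an immune
#' module up in dHGP metastases only, metabolism/cell-cycle up in rHGP
#' primaries and metastases, and a 9-gene fibrosis panel up in the normal
#' liver of dHGP patients.
#'
#' Lesion counts per patient are allocated deterministically so the default
#' design yields 47 dHGP and 43 rHGP metastatic lesions (90 L samples; 160
#' expression columns in total with the 35 C and 35 Ln samples).
#'
#' @param n_dhgp,n_rhgp Numbers of pure dHGP / rHGP patients.
#' @param lesions_dhgp,lesions_rhgp Total metastatic lesions per HGP class.
#' @param lesion_range Allowed per-patient lesion counts (inclusive bounds).
#' @param n_genes Total genes simulated.
#' @param module_sizes Named list of planted module sizes; `ln_fibrosis`
#'   must match the length of `ln_genes`.
#' @param effect_log2fc Named list of planted log2 fold changes per module.
#' @param sigma Biological standard deviation on the log2 scale.
#' @param baseline_mean,baseline_sd Gene baseline log2 mean distribution.
#' @param ln_genes Names of the normal-liver fibrosis panel. Eight genes of
#'   the panel are fibrosis-associated symbols; the ninth is a configurable
#'   placeholder.
#' @param base_hazard Monthly relapse hazard of the low-risk (dHGP) stratum.
#' @param hazard_ratio Relapse hazard multiplier for non-dHGP patients.
#' @param followup_horizon Administrative censoring horizon in months.
#' @param seed Default RNG seed used by [simulate_cohort()].
#'
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_dhgp = 20, n_rhgp = 15,
                          lesions_dhgp = 47, lesions_rhgp = 43,
                          lesion_range = c(1L, 4L),
                          n_genes = 5000,
                          module_sizes = list(emt_angio = 150, immune = 100,
                                              metabolism_cellcycle = 120,
                                              ln_fibrosis = 9),
                          effect_log2fc = list(emt_angio = 1.5, immune = 1.5,
                                               metabolism_cellcycle = 1.5,
                                               ln_fibrosis = 0.8),
                          sigma = 0.5,
                          baseline_mean = 5, baseline_sd = 2,
                          ln_genes = c("LUM", "LOXL4", "EPHA3", "ITGBL1",
                                       "NALCN", "MOXD1", "EFEMP1", "DTNA",
                                       "LN9_G9"),
                          base_hazard = 0.03, hazard_ratio = 2.5,
                          followup_horizon = 24,
                          seed = 1L) {
  modules <- c("emt_angio", "immune", "metabolism_cellcycle", "ln_fibrosis")
  if (!setequal(names(module_sizes), modules) ||
      !setequal(names(effect_log2fc), modules)) {
    abort(paste0("module_sizes and effect_log2fc must name exactly: ",
                 paste(modules, collapse = ", ")))
  }
  if (module_sizes$ln_fibrosis != length(ln_genes)) {
    abort("module_sizes$ln_fibrosis must equal length(ln_genes)")
  }
  if (sum(unlist(module_sizes)) > n_genes) {
    abort("planted module sizes exceed n_genes")
  }
  if (!all(is.finite(unlist(effect_log2fc)))) abort("effects must be finite")
  d <- list(n_dhgp = n_dhgp, n_rhgp = n_rhgp,
            lesions_dhgp = lesions_dhgp, lesions_rhgp = lesions_rhgp,
            lesion_range = as.integer(lesion_range),
            n_genes = as.integer(n_genes),
            module_sizes = map(module_sizes, as.integer),
            effect_log2fc = map(effect_log2fc, as.numeric),
            sigma = sigma, baseline_mean = baseline_mean,
            baseline_sd = baseline_sd, ln_genes = ln_genes,
            base_hazard = base_hazard, hazard_ratio = hazard_ratio,
            followup_horizon = followup_horizon, seed = as.integer(seed))
  # the deterministic allocation must be feasible within the lesion bounds
  allocate_lesions(d$lesions_dhgp, d$n_dhgp, d$lesion_range)
  allocate_lesions(d$lesions_rhgp, d$n_rhgp, d$lesion_range)
  structure(d, class = "cohort_design")
}

# Deterministic lesion allocation: floor(total/n) each, remainder to the
# first patients, all counts constrained to the allowed range.
allocate_lesions <- function(total, n, range) {
  base <- total %/% n
  rem <- total %% n
  counts <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
  if (any(counts < range[1]) || any(counts > range[2])) {
    abort(paste0("cannot allocate ", total, " lesions over ", n,
                 " patients within ", range[1], "-", range[2], " per patient"))
  }
  counts
}

#' Simulate a matched C/L/Ln cohort with planted HGP modules
#'
#' Expression is log2-normal: each gene has a baseline log2 mean drawn from
#' `Normal(baseline_mean, baseline_sd)`; a sample's value is
#' `2^(mean + planted effect + Normal(0, sigma))`, after which every column
#' is scaled to TPM (sum 1e6). Planted effects follow the seed-and-soil
#' structure: `emt_angio` up in dHGP C and L samples, `immune` up in dHGP L
#' only, `metabolism_cellcycle` up in rHGP C and L, `ln_fibrosis` up in
#' dHGP Ln only. Relapse-free survival is exponential with the non-dHGP
#' hazard multiplied by `hazard_ratio`, administratively censored at the
#' follow-up horizon. Deterministic given the seed.
#'
#' @param design A [cohort_design()].
#' @param seed RNG seed; defaults to the design's seed.
#' @return An `hgp_cohort` list with elements `expression` (TPM tibble),
#'   `annotation`, `clinical`, `modules` (gene-set tibble of planted
#'   modules), `truth` (planted memberships and effects) and `design`.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(seed, {
    ms <- design$module_sizes
    n_mod <- sum(unlist(ms))
    gene_ids <- sprintf("G%05d", seq_len(design$n_genes))
    # planted modules occupy the first rows; the fibrosis panel keeps its
    # gene symbols
    idx <- split(seq_len(n_mod),
                 rep(names(ms), times = unlist(ms)[names(ms)]))
    gene_ids[idx$ln_fibrosis] <- design$ln_genes
    modules <- map(idx, ~ gene_ids[.x])

    pats <- sprintf("P%02d", seq_len(design$n_dhgp + design$n_rhgp))
    hgp <- rep(c("dHGP", "rHGP"), c(design$n_dhgp, design$n_rhgp))
    lesions <- c(
      allocate_lesions(design$lesions_dhgp, design$n_dhgp, design$lesion_range),
      allocate_lesions(design$lesions_rhgp, design$n_rhgp, design$lesion_range))

    ann <- bind_rows(
      tibble(sample_id = paste0(pats, "_C"), patient_id = pats,
             tissue = "C", hgp = hgp),
      tibble(sample_id = paste0(pats, "_Ln"), patient_id = pats,
             tissue = "Ln", hgp = hgp),
      bind_rows(pmap(list(pats, hgp, lesions), function(p, h, k) {
        tibble(sample_id = paste0(p, "_L", seq_len(k)),
               patient_id = p, tissue = "L", hgp = h)
      })))

    mu <- rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
    eff <- matrix(0, design$n_genes, nrow(ann),
                  dimnames = list(gene_ids, ann$sample_id))
    is_d <- ann$hgp == "dHGP"
    e <- design$effect_log2fc
    eff[idx$emt_angio, is_d & ann$tissue %in% c("C", "L")] <- e$emt_angio
    eff[idx$immune, is_d & ann$tissue == "L"] <- e$immune
    eff[idx$metabolism_cellcycle,
        !is_d & ann$tissue %in% c("C", "L")] <- e$metabolism_cellcycle
    eff[idx$ln_fibrosis, is_d & ann$tissue == "Ln"] <- e$ln_fibrosis

    noise <- matrix(rnorm(length(eff), 0, design$sigma), nrow(eff))
    vals <- 2^(mu + eff + noise)
    vals <- sweep(vals, 2, colSums(vals) / 1e6, "/")
    expr <- expr_tibble(vals)

    clinical <- simulate_clinical(pats, hgp, design)

    structure(list(
      expression = expr,
      annotation = ann,
      clinical = clinical,
      modules = as_gene_sets(modules),
      truth = list(modules = modules,
                   effect_log2fc = e, sigma = design$sigma, seed = seed),
      design = design), class = "hgp_cohort")
  })
}

# Clinical covariates at frequencies typical of a resectable-CRLM cohort;
# relapse-free survival exponential with the configured hazard structure.
simulate_clinical <- function(pats, hgp, design) {
  n <- length(pats)
  is_d <- hgp == "dHGP"
  hazard <- design$base_hazard * ifelse(is_d, 1, design$hazard_ratio)
  t_raw <- rexp(n, hazard)
  H <- design$followup_horizon
  tibble(
    patient_id = pats,
    hgp = hgp,
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.71, 0.29)),
    location = sample(c("left_rectum", "right"), n, TRUE, prob = c(0.69, 0.31)),
    pt_stage = sample(c("T1-2", "T3", "T4"), n, TRUE, prob = c(0.09, 0.83, 0.08)),
    pn_stage = sample(c("N0", "N1", "N2"), n, TRUE, prob = c(0.49, 0.37, 0.14)),
    preop_chemo = sample(c("yes", "no"), n, TRUE, prob = c(0.89, 0.11)),
    rfs_time_months = pmin(t_raw, H),
    rfs_event = t_raw <= H)
}

#' Write a simulated cohort to disk
#'
#' Emits the four canonical tables (expression, annotation, clinical TSV
#' and planted-module GMT) plus a JSON record of the planted truth.
#'
#' @param cohort An `hgp_cohort` from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hgp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    modules = file.path(dir, "modules.gmt"),
    truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths["expression"])
  write_annotation(cohort$annotation, paths["annotation"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_gmt(cohort$modules, paths["modules"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @return An `hgp_cohort` list (without the design object).
#' @export
read_cohort <- function(dir) {
  structure(list(
    expression = read_expression(file.path(dir, "expression.tsv")),
    annotation = read_annotation(file.path(dir, "annotation.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    modules = read_gmt(file.path(dir, "modules.gmt")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE),
    design = NULL), class = "hgp_cohort")
}
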