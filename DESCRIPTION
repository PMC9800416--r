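Package: seedsoil
Title: Seed-and-Soil Transcriptomic Analysis of Histopathological Growth
    Patterns in Colorectal Liver Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline linking the histopathological growth pattern
    (HGP) of colorectal cancer liver metastases to expression programs of
    the primary tumor ("seed") and the normal liver ("soil"). Provides
    differential expression on TPM matrices with Wilcoxon rank-sum tests
    and Benjamini-Hochberg FDR control, construction of desmoplastic- and
    replacement-HGP signatures by intersecting primary and metastasis DEG
    sets, single-sample gene-set enrichment (ssGSEA) scoring with the
    derived C-score (seed) and Ln-score (soil) statistics, median-split
    seed-soil quadrant classification with ROC evaluation, unsupervised
    immune/stromal transcriptome subtyping of metastases, a composite
    HGP + subtype relapse risk score, and Kaplan-Meier / log-rank / Cox
    survival analysis of the 6-month relapse-free survival endpoint. A
    synthetic cohort generator with planted expression modules makes every
    stage testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
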