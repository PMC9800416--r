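---
title: "Seed-and-soil analysis of HGPs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-soil analysis of HGPs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedsoil)
```

## The scientific question

Colorectal cancer liver metastases grow against the liver in two dominant
histopathological growth patterns (HGPs): *desmoplastic* (dHGP), where a
fibrous rim separates tumor from liver, and *replacement* (rHGP), where
tumor cells replace hepatocytes along the liver cell plates. The pattern is
prognostic, but it is read from H&E morphology; seedsoil implements a
transcriptomic account of where the pattern comes from, using matched
samples from each patient: the primary colorectal lesion (C, the "seed"),
the liver metastases (L), and tumor-distant normal liver (Ln, the "soil").

The working model is that the HGP is jointly determined by a seed program
(EMT/angiogenesis/stroma-high primaries tend to produce desmoplastic
metastases; metabolism/cell-cycle-high primaries produce replacement
metastases) and a soil program (a fibrosis-prone normal liver favors the
desmoplastic pattern). The package turns that model into two per-patient
statistics and a composite risk score, and ships a synthetic cohort
generator so the whole chain is testable without restricted patient data.

## The analysis chain

1. **Differential expression** (`run_de`). Per gene, a two-sided Wilcoxon
   rank-sum test of dHGP versus rHGP samples on TPM values, with
   Benjamini–Hochberg adjustment across genes and a dual significance gate:
   a gene is called only when `|log2FC| > t` *and* `FDR < 0.05`. The tumor
   comparisons (L, lesion-level, 47 vs 43; C, patient-level, 20 vs 15) use
   `t = 1`; the much quieter normal-liver comparison uses `t = 0.5`. The
   fold change is `log2((mean TPM_A + 1)/(mean TPM_B + 1))`; the
   pseudocount stabilizes genes near zero. P-values use the exact Wilcoxon
   null distribution when both groups have at most 25 samples and the gene
   is tie-free, and the normal approximation with tie and continuity
   corrections otherwise; zero-variance genes get `p = 1` rather than being
   dropped, so every input gene appears in the result.

2. **Signature construction** (`intersect_up_sets`). The seed signatures
   are the genes significant *with the same direction* in both the primary
   and the metastasis comparison — the expression programs a metastasis
   inherits from its seed. The soil panel is the set of genes up-regulated
   in dHGP normal liver.

3. **ssGSEA scoring** (`ssgsea_es`, `score_signatures`,
   `compute_scores`). Within each sample, genes are ranked by decreasing
   expression (ties broken lexicographically by gene id, so scores are
   reproducible); position $i$ of $N$ carries weight $(N - i + 1)^\alpha$
   if the gene is in the set. With $P_{in}(i)$ the weighted fraction of set
   genes seen by position $i$ and $P_{out}(i)$ the plain fraction of
   non-set genes, the enrichment score is the full running-sum integral
   $\sum_i (P_{in}(i) - P_{out}(i))$. Because weights depend on ranks, not
   values, the score is invariant to any monotone transform of a sample's
   expression — the property the test suite leans on. The seed statistic is
   **C-score = dHGP score − rHGP score** on the primary sample; the soil
   statistic (**Ln-score**) is the panel score on the normal-liver sample.

4. **Seed–soil classification** (`median_split`, `quadrant_classify`,
   `cluster_patients`, `evaluate_predictors`). Both scores are
   dichotomized at their cohort medians; concordant-high patients are the
   predicted dHGP corner, concordant-low the predicted rHGP corner, and the
   association is tested by Pearson chi-square. Predictive accuracy for the
   HGP label is quantified by ROC AUC for each score and for their
   in-sample logistic combination.

5. **Transcriptome subtyping and risk** (`assign_subtypes`,
   `patient_subtype`, `risk_score`). Lesions are clustered on z-scored
   signature profiles (Euclidean distance, Ward linkage, `k = 3`) and the
   clusters ranked by mean immune + stromal signature score into High-IS,
   Medium-IS and Low-IS. A patient scores one risk point for non-dHGP
   status and one for carrying a Medium-IS lesion; 2 points is high risk.

6. **Survival** (`km_curve`, `log_rank`, `cox_univariate`, `rfs6m`).
   Relapse-free survival is censored administratively at 6 months (an
   event at exactly the horizon counts as an event — the boundary rule is
   stated because it is otherwise ambiguous) and compared across HGP and
   risk groups by Kaplan–Meier curves, the log-rank test, and a univariate
   Cox model with Breslow tie handling (Newton–Raphson, tolerance 1e-9).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lfc` gates (L, C / Ln) | 1 / 0.5 | log2 fold-change gate per comparison |
| `fdr` gate | 0.05 | BH-adjusted significance gate |
| `alpha` | 0.25 | ssGSEA rank-weight exponent (the conventional value) |
| `normalize_scores` | TRUE | divide all enrichment scores by the joint max−min range |
| `patient_linkage` | complete | linkage for the two-score patient clustering |
| `subtype_linkage`, `subtype_k` | ward, 3 | lesion subtyping |
| `patient_rule` | any_medium | how lesion subtypes become a patient flag |
| `horizon` | 6 months | early-relapse endpoint |
| `min_signature_size` | 9 | fallback signature size (below) |

## What the synthetic cohort emulates

`cohort_design()` defaults describe a 35-patient surgical cohort: 20 dHGP
and 15 rHGP patients, each with one C and one Ln sample, and 47 + 43 = 90
metastatic lesions allocated deterministically (2–3 per patient), 160
expression columns in all. Expression is log2-normal: gene baselines drawn
from Normal(5, 2) on the log2 scale, per-sample biological noise
Normal(0, 0.5), and planted module effects added on the log2 scale before
each column is scaled to TPM:

* `emt_angio` (150 genes, +1.5 log2) up in dHGP C **and** L — the
  inherited seed program;
* `immune` (100 genes, +1.5) up in dHGP L **only** — the
  metastasis-specific immune infiltrate, deliberately *not* inherited;
* `metabolism_cellcycle` (120 genes, +1.5) up in rHGP C and L;
* `ln_fibrosis` (9 genes, +0.8) up in dHGP Ln only — the fibrosis-prone
  soil. Eight panel members are named fibrosis-associated genes (LUM,
  LOXL4, EPHA3, ITGBL1, NALCN, MOXD1, EFEMP1, DTNA); the ninth is the
  placeholder `LN9_G9` and the panel is configurable.

Relapse-free survival is exponential with a monthly baseline hazard of
0.03 for dHGP patients, multiplied by a hazard ratio of 2.5 for non-dHGP
patients, censored administratively at 24 months. Only the relative
ordering of the groups matters for the rank-based survival tests, so the
exponential form is the simplest adequate choice.

A log2-normal TPM model was chosen over a negative-binomial count model
because every analysis step is rank-based or operates on TPM directly;
the distributional family beyond its ranks is irrelevant to the chain
being tested. What the generator does **not** emulate: within-patient
correlation between lesions beyond the shared class effect, mixed-HGP
(impure) lesions (representable only as labels), chemotherapy effects,
compositional library artifacts, or realistic gene–gene correlation. A
passing suite therefore shows the chain recovers structure *of the planted
kind*; it does not certify performance on real cohorts, where effects are
smaller, correlated, and confounded. One visible consequence of the clean
class separation: the three-subtype step usually splits the dHGP lesions
into High-IS and Medium-IS while all rHGP lesions land in Low-IS, so the
composite risk score can produce an empty high-risk stratum (no rHGP
patient carries a Medium-IS lesion); the survival stage then reports the
Kaplan–Meier curve for the single group and skips the two-group tests.

## Numerical and degenerate-input choices

* **Exact vs approximate Wilcoxon.** The exact null distribution is used
  whenever both groups have ≤ 25 samples and the values are tie-free,
  which covers the 20-vs-15 patient-level comparisons; this matters for
  the Ln comparison, where a 9-gene effect must survive BH across
  thousands of genes and the far tail of the normal approximation is
  conservative.
* **Empty signatures.** Under the default generator conditions the
  normal-liver comparison occasionally yields *no* genes passing both
  gates (its planted effect is deliberately subtle). The pipeline then
  falls back to the top `min_signature_size` direction-concordant genes by
  p-value, with a logged warning; the DE tables still record the honest
  empty call. An analysis that aborted instead would be useless on quiet
  cohorts.
* **Median ties go low.** `median_split` assigns values equal to the
  median to the low group — deterministic, and conservative toward the
  high (dHGP-like) call.
* **Cluster label identifiability.** Subtype labels are assigned by
  ranking clusters on their mean immune + stromal score, so they are
  invariant to cluster index permutation and to lesion input order.
* **Perfect separation.** The logistic marker combination detects
  separation and falls back to the sum of rank-standardized markers; the
  ROC direction is fixed (higher score = more dHGP-like), so an
  uninformative marker scores near 0.5 instead of being flipped to 0.5+.
* **Normalization degeneracy.** If all enrichment scores are equal, range
  normalization is skipped with a warning rather than dividing by zero.
* **TPM hygiene.** Negative, missing, or non-finite expression values are
  rejected with coordinates, never imputed; duplicate gene or sample ids
  are errors; TPM renormalization is idempotent and column sums are
  checked to a relative tolerance of 1e-6.

## Open design points and how they were resolved

* The gene-identifier namespace is left opaque (case-sensitive strings);
  no symbol/Ensembl mapping is attempted.
* Whether the two seed scores should be normalized before differencing is
  not determined by the method's description; both modes exist behind
  `normalize_scores`, with cohort-joint range normalization (the original
  ssGSEA convention) as the default.
* The combination rule behind the joint C+Ln ROC is an in-sample logistic
  model — the simplest choice consistent with reporting a single combined
  AUC; it is documented as in-sample, not cross-validated.
* Lesion-level units are used for the L-tissue comparison (47 vs 43),
  accepting within-patient correlation.
* Multi-lesion patients map to a subtype point through `any_medium` by
  default (a single Medium-IS lesion carries the point); a `majority` rule
  with ties broken toward Medium-IS is provided.
* Cox hazard ratios for the 6-month endpoint are computed on the censored
  data; the Kaplan–Meier curves and log-rank test are reported alongside,
  so either reading of "HR at six months" is available.

## Problem sizes used by the automated checks

The test suite and the acceptance script simulate cohorts at 600–2000
genes with proportionally scaled modules (the full 5000-gene default is
exercised in the end-to-end run), 20 replicate seeds for the
sensitivity/FDR and marker-combination properties, 500–2000 replicates
for the survival calibration checks, and 100 random instances for the
ssGSEA reference comparison. These sizes were chosen so each property is
measured with Monte-Carlo error well inside its asserted margin.

## Known limitations

Single-sample enrichment scores are compositional and rank-based: they
move when library composition shifts, even without biological change. The
in-sample combined AUC is optimistic by construction. The subtype step
fixes `k = 3` by design rather than selecting it from the data. None of
the survival tooling handles competing risks, time-varying effects, or
multivariable adjustment — deliberately outside this package's scope.
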