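# subtypeAdmix

Intrinsic-subtype admixture deconvolution for bulk breast-tumor
transcriptomes.

PAM50 profiling assigns each breast cancer a single intrinsic subtype
(Luminal A, Luminal B, HER2-enriched, Basal-like), yet a bulk sample from
an individual tumor can carry transcriptional evidence of more than one
subtype. `subtypeAdmix` quantifies that admixture: it estimates, for every
tumor, the proportion of its transcriptome attributable to each of the
four major subtypes, stratifies the (nominally most favorable) Luminal A
tumors by purity, and asks whether admixed tumors look and behave worse —
clinically, molecularly, and in overall survival.

## The model

Given a nonnegative expression matrix `X ∈ R^{m×n}` (m genes, n tumors)
and one-hot PAM50 labels `L ∈ R^{4×n}`, the package fits a
**semi-supervised non-negative matrix factorization (ssNMF)**:

```
min_{A,B,S ≥ 0}  || X − A S ||_F² + λ || L − B S ||_F²
```

where `A (m×k)` holds k nonnegative metagenes, `S (k×n)` the per-tumor
mixing coefficients, and `B (4×k)` maps metagenes onto the four subtype
labels. The label reconstruction `BS`, column-normalized to sum to one,
gives the per-tumor subtype proportions `(pLumA, pLumB, pHER2, pBasal)`.
The solver uses Lee–Seung-style multiplicative updates on the augmented
system `[X; √λ·L] ≈ [A; √λ·B]·S`, which keeps the objective monotone
non-increasing; `k` and `λ` are chosen by five-fold cross-validation on
held-out PAM50 label accuracy (held-out coefficients come from
nonnegative least squares, so test labels never leak into the fit).

Around the factorization the package provides:

- a **synthetic two-cohort generator** with known ground-truth admixture,
  batch effects, admixture-linked clinical covariates, and survival
  calibrated to a chosen extreme-quartile hazard ratio;
- cohort **merging/normalization** (gene intersection, within-cohort
  z-score, min-shift to nonnegative) and **nearest-centroid PAM50
  assignment** with Normal / Claudin-low exclusions;
- purity metrics: **quartile strata** of pLumA, **exclusive top-quartile
  (eQ4)** subsets, **Shannon entropy** (bits), and the Mahalanobis
  **Distance Ratio Criteria (DRC)** comparator;
- a configurable **signature engine** (gene-set mean proliferation score,
  centroid-correlation risk-of-recurrence, grouped-linear
  Oncotype-DX-style score, template-correlation MammaPrint-style call);
- the **statistical battery**: Welch t and Fisher exact extreme-stratum
  tests, Cochran–Armitage / regression trend tests, cross-classified
  means, Kaplan–Meier curves with Greenwood CIs, and unadjusted/adjusted
  Cox proportional-hazards models (Efron ties, purest stratum referent).

## Worked example

```r
library(subtypeAdmix)

# simulate two cohorts with known admixture, run the full pipeline
run <- run_pipeline(default_run_config(n_per_cohort = 400, master_seed = 3))

run$model
#> ssnmf_model: 500 genes, 800 samples, k = 8, lambda = 1
#>   objective 7166.15 after 2000 iterations (max_iter reached)

head(run$admixture[, c("sample_id", "pLumA", "pLumB", "pHER2", "pBasal",
                       "entropy_bits", "purity_quartile", "eq4_subtype")], 4)
#>    sample_id     pLumA      pLumB        pHER2     pBasal entropy_bits purity_quartile eq4_subtype
#> 1 simA_s0008 0.8164008 0.11642458 4.431687e-02 0.02285779    0.9239815               3        LumB
#> 2 simA_s0017 0.6985287 0.09397519 7.233656e-02 0.13515957    1.3465022               2        none
#> 3 simA_s0027 0.9578358 0.01826112 6.879395e-14 0.02390311    0.2937466               4        LumA
#> 4 simA_s0036 0.8065393 0.10500634 5.640633e-02 0.03204798    0.9846455               3        none

run$cox
#> Cox PH (Efron ties): 211 subjects, 109 events
#>   level    hr ci_low ci_high        p
#> 1     1 2.665  1.511   4.701 0.000711
#> 2     2 1.731  0.961   3.118 0.067600
#> 3     3 1.776  0.972   3.245 0.061800
#> trend p = 0.00117

round(compare_purity_metrics(run$admixture)$spearman, 3)
#>             pLumA neg_entropy neg_drc
#> pLumA       1.000       0.958   0.620
#> neg_entropy 0.958       1.000   0.559
#> neg_drc     0.620       0.559   1.000
```

Reading the output: the pipeline simulated two 400-tumor cohorts whose
survival generator doubles the hazard of the most admixed Luminal A
quartile relative to the purest. Among the 211 simulated LumA cases the
estimated Q1-vs-Q4 hazard ratio is 2.67 (95% CI 1.51–4.70) with a trend
p of 0.0012 across quartiles — the planted purity–survival gradient is
recovered. Shannon entropy and pLumA rank tumors almost identically
(Spearman ρ ≈ 0.96) while the PAM50-gene-only DRC tracks purity more
loosely (ρ ≈ 0.6), matching its role as a coarser comparator. The run
directory additionally contains the admixture table, per-subtype
proportion histograms, quartile comparison tables, KM curves, the
cross-classified basal-marker (EGFR) means, and the serialized model with
a manifest.

Shipped reference files in `inst/extdata/` (the PAM50 centroid table and
the MammaPrint-style template) are *synthetic*, clearly labelled stand-ins
with the correct structure; supply your own tables for real analyses.

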