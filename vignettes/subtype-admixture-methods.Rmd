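---
title: "Quantifying intrinsic-subtype admixture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrinsic-subtype admixture: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeAdmix)
```

## The problem

Bulk transcriptome profiling averages over every cell in a tumor sample.
A breast cancer called Luminal A by PAM50 nearest-centroid classification
may therefore hide substantial transcriptional contributions from the
Luminal B, HER2-enriched, or Basal-like programs. `subtypeAdmix` treats a
bulk expression profile as a nonnegative mixture of metagenes, ties a
subset of that mixture to the four subtype labels, and reads off
per-tumor subtype proportions. Downstream, it asks the epidemiological
question: do Luminal A tumors with low purity (heavy admixture) carry
worse clinical features and shorter overall survival?

## The factorization

With nonnegative expression `X` (m genes by n tumors) and one-hot labels
`L` (4 by n), the package minimizes

$$\min_{A,B,S \ge 0} \; \|X - AS\|_F^2 \; + \; \lambda \, \|L - BS\|_F^2 ,$$

over metagenes `A` (m by k), mixing coefficients `S` (k by n), and the
label basis `B` (4 by k). Equivalently this is a plain NMF of the
augmented matrix $[X; \sqrt{\lambda} L]$ with augmented basis
$[A; \sqrt{\lambda} B]$, which is how the solver is implemented:
Lee–Seung multiplicative updates on the augmented system decouple into
separate `A` and `B` updates plus a combined `S` update, and inherit the
classical monotonicity guarantee — the objective never increases (the
test suite enforces this with a 1e-9 relative slack for floating-point
rounding).

Key numerical choices:

- **Initialization.** All factors start uniform(0, 1) scaled by
  $\sqrt{\mathrm{mean}(X)/k}$ from the config seed, so magnitudes are
  commensurate with the data and every fit is exactly reproducible.
- **Stabilizer.** `eps = 1e-10` is added to update denominators. The
  formal constraint is strict positivity; in practice entries may reach
  exact zero and stay there (standard multiplicative-update
  "zero-locking"), which we accept.
- **Convergence.** Stop when the relative objective change over a
  10-iteration window drops below `tol` (default 1e-5), or at `max_iter`
  (default 2000). Near an exactly factorizable optimum the objective
  decays roughly like 1/t, so tests that chase the exact optimum raise
  `max_iter` substantially instead of loosening the target.
- **Degenerate mode.** `lam = 0` gives unsupervised NMF; a rank-1
  unsupervised fit on a nonnegative matrix must reach the residual after
  removing the leading singular component (Perron–Frobenius guarantees a
  nonnegative leading pair), which the tests use as an independent
  oracle.

## Proportions, held-out inference, and hyperparameters

The label reconstruction `BS` is interpreted as unnormalized subtype
proportion estimates; each column is divided by its sum to give
`(pLumA, pLumB, pHER2, pBasal)`. A column summing to (numerically) zero
is an error naming the sample, not a silent NaN.

`k` and `λ` are selected by five-fold cross-validation, stratified by
subtype, scoring PAM50 label accuracy on held-out folds. Because held-out
labels must not inform the fit, held-out mixing coefficients solve the
label-free nonnegative least-squares problem
$\min_{s \ge 0} \|x - A s\|^2$ (via `pracma::lsqnonneg`), and the
predicted class is the argmax of `B s`. Accuracy is computed per fold and
averaged; ties on the grid go to smaller `k`, then smaller `λ`. Default
grids are k ∈ {4, 6, 8, 10, 12, 16, 20} and λ ∈ {0.01, 0.1, 1, 10, 100},
fully configurable; the acceptance checks use the reduced grid
k ∈ {4, 8, 12}, λ ∈ {0.1, 1, 10}, which already recovers synthetic truth
essentially perfectly. On the reference synthetic cohort all grid points
reach CV accuracy 1.0, and the tie-break selects k = 4 — with clean
block structure four metagenes suffice for classification, and the
fitted proportions still correlate with truth at r > 0.99 per subtype.

## Purity metrics

- **Quartiles.** Samples are ranked ascending by pLumA and cut into four
  contiguous rank groups with sizes as equal as possible; when n mod 4 ≠ 0
  the extra members go to the lowest-numbered quartiles (n = 10 gives
  3, 3, 2, 2). Ties keep stable input order, so stratification is
  deterministic. Q1 is the most admixed, Q4 the purest. Rank-based
  near-equal groups (rather than value cut-points) match how near-equal
  quartile sizes are reported in practice; the remainder-to-low rule is
  this package's convention.
- **eQ4.** For each subtype, its top quartile is flagged; a sample is
  `eQ4-s` if it is top-quartile for subtype s and for no other subtype.
  The four eQ4 sets are disjoint by construction.
- **Shannon entropy** is reported in bits (base 2), so the 4-class
  maximum is exactly 2 at the uniform mixture and 0 at a pure sample.
- **DRC** (Distance Ratio Criteria) is the Mahalanobis distance to the
  assigned subtype's centroid divided by the distance to the nearest
  alternate centroid, over the PAM50 genes. The shared covariance is the
  pooled within-subtype covariance with ridge shrinkage
  $(1-\gamma)\Sigma + \gamma\,\mathrm{diag}(\Sigma)$, default γ = 0.1 — a
  50-dimensional covariance estimated at realistic class sizes needs
  stabilization. Distances are computed through a Cholesky solve and
  verified against direct covariance inversion to 1e-10.
- **Histograms.** Each subtype's proportion range is divided into 100
  equal-width bins (last bin right-closed); constant input collapses to a
  flagged single bin.

## The synthetic study conditions

The generator exists so that every stage can be tested against known
ground truth without external downloads. Its defaults are the reference
conditions used by the tests and the acceptance script:

- **Metagenes:** m = 500 genes, k_true = 8 metagenes, each with a
  disjoint marker block (~m/k genes) elevated 10-fold (gamma-distributed
  weights, shape 2); metagenes assigned round-robin to the four subtypes.
- **Admixture:** each sample draws a uniformly random dominant subtype
  and Dirichlet proportions with concentration (8, 1, 1, 1) rotated so
  the dominant component is largest in expectation — "mostly one subtype
  with non-zero admixture of the rest". The draw is then permuted so the
  dominant subtype truly carries the largest realized mass, making the
  recorded label equal the argmax of the true proportions for every
  sample (a hard invariant the tests rely on).
- **Expression:** basis × weights, times a per-cohort scale (second
  cohort 1.6) plus offset (0.5) emulating platform batch effects, plus
  centered Gaussian noise (sd 0.1) clipped at zero — the simplest noise
  respecting NMF's nonnegativity.
- **Clinical covariates:** logistic links in the admixture mass
  (1 − pLumA) and in individual alternate-subtype proportions, with
  reference coefficients oriented after the associations reported for
  luminal-A cohorts (admixture → node positivity, size, stage, TP53;
  HER2 admixture → HER2 positivity; LumB admixture → PR negativity;
  basal admixture → younger age; purity → PIK3CA/CBFB).
- **Survival:** exponential (constant hazard) with log-hazard
  proportional to (1 − pLumA), baseline rate ln 2 / 230 per month
  (median ≈ 230 months for a pure tumor, on the scale of long
  breast-cancer follow-up), uniform administrative censoring over 300
  months. `calibrate_hazard()` sets the coefficient so that the mean
  log-hazard gap between the realized extreme pLumA quartiles equals
  ln 2 — i.e. a target extreme-quartile hazard ratio of 2, the effect
  size of the kind reported for purity-stratified luminal-A survival.
  In the two-cohort pipeline the calibration is done on the
  LumA-dominant subset, because that is the population the survival
  stage stratifies.

What the generator does **not** emulate: gene–gene correlation beyond
block structure, count-like noise, copy number, Normal/Claudin-low
profiles, or non-proportional hazards. Passing tests therefore certify
the estimator and the statistical machinery under a well-specified
admixture model — not performance on any real cohort.

Problem sizes in the tests and acceptance script (cohorts of 100–400
samples per arm, 20–100 survival replicates) were chosen as the smallest
sizes at which the planted effects are comfortably identifiable.

## Cohort handling conventions

- **Merging.** Genes are intersected across cohorts (sorted order); with
  `normalization = "zscore"` each gene is centered/scaled within each
  cohort, removing exactly the location/scale batch effects the generator
  injects. Zero-variance genes cannot be z-scored and are dropped with a
  reported count. Merging is order-insensitive up to column order.
- **Nonnegativity.** Z-scored data are negative; each gene row is shifted
  by its minimum (row minimum becomes exactly 0), preserving all
  within-row differences and retaining the shift vector for provenance.
  The published pre-processing behind real cohort merges is not fully
  specified in the public record; this explicit, reversible convention is
  documented rather than claimed to replicate any particular pipeline.
- **PAM50 calls.** Nearest-centroid by Spearman correlation (default;
  robust to monotone platform distortions — calls are provably invariant
  to strictly monotone per-sample transforms), Pearson by option. Ties
  break by the fixed order LumA, LumB, HER2, Basal, Normal. At least 25
  of the 50 centroid genes must be measured. Normal-like calls are
  excluded from all cohorts and Claudin-low calls from METABRIC-like
  cohorts only, mirroring the exclusion conventions of the source
  datasets. The packaged centroid table is a clearly labelled synthetic
  stand-in with the canonical gene symbols; real analyses should supply a
  platform-appropriate centroid file.
- **LumA restriction.** All purity stratification, eQ4 construction,
  feature comparisons, and survival analyses run on the LumA-assigned
  subset; proportions remain available for every sample.

## Signature engine

Four formula kinds cover the molecular score variables: an unweighted
gene-set mean (the 11-gene proliferation score), a linear combination of
subtype-centroid correlations (risk of recurrence; coefficients
−0.34 LumA, +0.23 LumB, +0.12 HER2, +0.05 Basal, affinely mapped to a
0–100 research scale), a grouped linear score with per-group floors and
ordered risk cutpoints (the 21-gene recurrence-score structure, cutpoints
18/31 with a lower-closed convention), and a template-correlation
threshold call (high risk strictly below 0.4). Definitions live in JSON
fixtures so the constants are auditable and replaceable. Because the
group floors were defined on a 0–15 reference-normalized scale, the
grouped score optionally min-max rescales each gene to that range first;
absolute score levels are cohort-dependent and explicitly not comparable
to commercial assays — only the formula structure and its linearity
properties are tested. Missing genes are tolerated down to 50% coverage
per signature (with warnings), since merged research matrices routinely
lose genes at intersection.

## Statistical stage

"Compare the extremes, test the trend": continuous features use two-tailed
Welch t-tests of the lowest versus highest stratum; binary features use
two-sided Fisher's exact tests on the extreme 2×2 (verified to 1e-12
against direct hypergeometric enumeration). Trend across ordered strata
uses Cochran–Armitage (`stats::prop.trend.test`) for binary features and
the least-squares slope test for continuous ones — the trend method and
missing-data policy are not uniquely dictated by common practice, so the
package fixes and documents these conventions (complete-case per feature,
with per-stratum counts reported). Survival uses the product-limit
estimator with Greenwood-based CIs; the median is the earliest time the
curve reaches 0.5 (undefined if never). Cox models use Efron tie handling
with the purest stratum as referent, in unadjusted form and adjusted for
age, tumor size, and stage (grade available as an optional extra), plus a
score-coded trend model. KM with no censoring equals the empirical
survivor function exactly, and the null log-rank rejects at the nominal
rate — both are enforced in the tests.

## Pipeline and reproducibility

`run_pipeline()` chains the stages from a single config; every stage seed
derives from the master seed by a fixed documented offset, so stages can
be re-run in isolation and two runs with one master seed are
byte-identical (enforced by test). All figure-level outputs are tidy CSVs
(histograms, comparison tables, KM curves, hazard ratios, cross-classified
means) plus the serialized model and a JSON manifest with seeds, sizes,
and input checksums. A deliberate design choice: no plotting layer is
required for any result — everything is numeric first.

## Known limitations

- Multiplicative updates converge to a stationary point, not a certified
  global optimum; different seeds can give different (equally valid)
  factorizations. The proportions, being normalized label
  reconstructions, are empirically stable across seeds at the reference
  conditions.
- The admixture model is linear; it cannot distinguish a tumor whose
  cells each express a mixed program from a tumor containing distinct
  subclonal populations.
- Exponential survival and logistic covariate links are convenient
  calibration devices, not biological claims.
- The shipped centroid and template fixtures are synthetic stand-ins;
  results on real data hinge on supplying genuine reference tables
  matched to the expression platform.
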