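---
title: "Centenarian-weighted methylation age clocks: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centenarian-weighted methylation age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centclock)
```

## The problem

DNA methylation age clocks are penalized regressions of chronological age on
CpG beta values. They are accurate in the age ranges where training data are
dense, but above ~90 years two things happen at once: samples become rare,
and shrinkage pulls predictions toward the training mean. The result is a
systematic underestimation of the oldest old — the regression-to-the-mean
effect. A clock intended to *verify age claims of centenarians* must counter
this, which this package does the way the field does: up-weight the rare
100+ samples (weight 10 versus 1) in the training loss, train on a wide
40+ age range, and validate with 20-fold cross-validation stratified into
40+/80+/100+ reporting bins.

This vignette documents the models, the simulator that stands in for the
access-restricted cohorts such analyses are usually run on, the numerical
choices, and the points where the design was genuinely open.

## The clock models

**Weighted elastic net.** `fit_weighted_elastic_net()` minimizes, with
normalized weights $v_i$,
$\frac12\sum_i v_i (y_i - \beta_0 - x_i^\top\beta)^2 +
\lambda(\alpha\|\beta\|_1 + \frac{1-\alpha}2\|\beta\|_2^2)$, $\alpha = 0.5$
by default. Implementation details that matter:

* Features are standardized *inside* the fit to weighted mean 0 and weighted
  mean-square 1; the constants are stored in the model so a serialized clock
  is portable. Observation weights enter every moment, which makes integer
  weights exactly equivalent to row duplication (a tested invariant).
* The $\lambda$ path has 100 log-spaced values from $\lambda_{max}$ (the
  smallest $\lambda$ with an all-zero solution) down to
  $10^{-4}\lambda_{max}$; coordinate descent uses warm starts, an active-set
  inner loop, tolerance $10^{-7}$ on the maximum standardized-coefficient
  change, and an iteration cap of $10^5$ per $\lambda$. Every solution is
  checked against the elastic-net KKT conditions in the test suite.
* For $p \le 512$ the solver uses covariance updates (maintaining the
  gradient from the Gram matrix) so each coordinate update is $O(p)$ rather
  than $O(n)$; beyond that it falls back to residual updates. This is purely
  an implementation choice — both routes solve the same objective.
* $\lambda$ is selected by K-fold cross-validation on the training data
  (10 folds by default), minimizing weighted out-of-fold squared error, with
  ties resolved toward the larger (more shrunken) $\lambda$.

**Neural network.** `fit_mlp()` is a fully-connected regressor with ReLU
hidden units, linear output, and weighted squared loss, trained full-batch
with Adam for a fixed epoch budget. The architecture (64, 32), learning rate
0.01, and budget of 600 epochs are fixed a priori and deliberately not tuned
per dataset; the published analyses this mirrors state that their network
hyperparameters were fixed in advance but do not print them, so these
defaults are declared, not inferred. With zero hidden layers the model
reduces to linear regression, which the tests exploit as an oracle.

**Age transform.** Predictions are in years, untransformed. Generic clock
definitions sometimes transform age before regression; nothing in the
source analyses specifies a transform for these clocks, so identity is used.

**Centenarian boundary.** Weight 10 applies at age $\ge 100.0$ exactly
(boundary inclusive).

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure the
downstream analyses assume, calibrated once to the printed marginals of the
reference multi-cohort training data (`reference_cohort_counts()`):

* **Scale.** Defaults are n = 600 samples and 2000 CpGs — the package-scale
  analogue of the reference data (n = 7039, 33,495 CpGs after
  pre-filtering). All analyses scale to larger configurations.
* **Ages.** A uniform body on [40, 95] mixed with a 100+ tail of
  shifted-exponential ages (mean 5.6 years above 100, truncated at 115),
  with tail weight 184/7039 ≈ 2.6% — matching the reference tail's
  105.6 ± 3.5 [100, 115] summary without modeling demography.
* **Sex.** 54.5% female; a block of 50 sex-linked CpGs is mean-offset by
  0.15 in females so QC PCA recovers sex as the leading structure, as real
  methylome PCAs do.
* **Trajectory classes.** 10% of (non-sex) CpGs gain methylation linearly
  with age, 10% lose it, 5% gain until a saturation age drawn from
  [55, 75] years and then level off, 75% are null. Slopes are drawn from
  1–3 × 10⁻³ per year on the beta scale. The saturating class mirrors the
  "leveling off" trajectories some promoter-flanking states show; the
  linear classes mirror canonical linear CpGs.
* **Noise.** Truncated Gaussian on the beta scale with SD
  $0.02 + 5\times10^{-4} \cdot \text{age}$, reproducing the increased
  late-life variability of real trajectories. A logit-normal alternative was
  considered and rejected as unnecessary for what the tests probe.
* **Batch.** Additive per-(cohort, CpG) offsets ~ N(0, 0.01) over 3
  cohorts: enough for batch structure to exist, small enough that age
  remains the dominant signal.
* **Annotation.** Each CpG gets exactly one chromatin-state label from a
  10-state universe; positively age-related CpGs are placed into the
  bivalent/polycomb-like states (BivProm1/2, ReprPC1) with odds 5, and PRC
  member binding (RING1/RNF2/BMI1; EED/SUZ12/EZH2) is drawn with elevated
  rates in those states, so both the state enrichment and the
  "at least two members" PRC rule are recoverable by construction.
* **Survival and biomarkers.** Each sample carries a latent age
  acceleration ~ N(0, 3 years); event times are exponential with hazard
  $0.01 \cdot 1.05^{\text{accel}} \cdot 1.08^{\text{age}-70}$ censored at 15
  years, and biomarkers are built as
  $t \cdot z(\text{accel}) + \sqrt{1-t^2}\,\varepsilon$ with target
  correlations alternating in sign across 0.04–0.17 — the magnitude range
  such clock-biomarker associations actually occupy.

**What the simulator does not emulate** — and hence what green tests do
*not* establish about real data: realistic genome coordinates and CpG-island
structure, cell-type composition and its age drift, pedigree correlation,
array normalization artifacts, and non-exponential mortality. The simulator
exists to make the *machinery* testable end to end, with planted truths the
pipeline must recover; it is not a generative model of a real methylome.

## Data preparation

Beta values follow the standard intensity formula
$\beta = \max(M,0) / [\max(M,0) + \max(U,0) + 100]$, strictly below 1 for
finite input. Pre-filtering keeps three groups — strongest positive age
correlations, strongest negative, and near-zero ($|r| \le$ 0.02 by default)
— with deterministic CpG-id tie-breaks; the group sizes are configuration
(defaults 1000/1000/500 at full scale, 100/100/50 at package scale) because
the design this mirrors states the three-group structure and the final CpG
count but not the thresholds. Correlations are computed on the whole
training set (the natural reading where nothing more specific is stated).
Outlier removal iteratively fits a preliminary clock and drops samples with
absolute residuals above 30 years (at most 3 rounds) — a criterion chosen to
catch platemap/labeling errors while being auditable through the returned
report; the threshold is intentionally generous since the purpose is gross
error removal, not trimming. Missing betas are mean-imputed per CpG with a
logged message.

## Downstream statistics

* **Age acceleration** is the raw OLS residual of predicted on chronological
  age; orthogonality to age (|r| < 10⁻¹⁰) is asserted, not assumed.
* **Cox models** maximize the Breslow-tied partial likelihood by Newton
  iterations (gradient norm < 10⁻⁸). Breslow was chosen over Efron as the
  common epidemiology default; with the near-continuous simulated times the
  difference is negligible. The timescale is follow-up time with age as a
  covariate. Per-stratum log hazard ratios are combined by inverse-variance
  fixed-effect meta-analysis.
* **Correlation meta-analysis** moves bicor estimates to the Fisher-z scale
  with SE $1/\sqrt{n-3}$ before inverse-variance combination, then
  back-transforms — the standard variance-stabilized construction; strata
  with fewer than 4 complete observations are skipped with a message.
* **bicor** uses the conventional tuning: deviations scaled by 9 × MAD
  (unscaled), bisquare weights, hard zero outside |u| ≥ 1, and a Pearson
  fallback with a warning when the MAD is zero.
* **EWAS** Z scores are probit transforms of the two-sided t-test p value
  carrying the sign of r — matching the construction of the standard
  screening implementations. p values live on the log10 scale internally
  (floored at 10⁻³²⁰) so that associations far beyond double precision
  survive; this matters because real EWAS of age produce p values like
  10⁻²⁰⁰⁰. Age-group bounds are lower-inclusive (a 40.0-year-old is
  "middle", a 90.0-year-old "old") — the interval notation in the source
  material is ambiguous at the boundaries, so the convention is fixed here.
* **Enrichment** reports the one-sided upper tail including the observed
  count, P(X ≥ k), as the enrichment p (depletion P(X ≤ k)); both tails are
  accumulated in log space from `lchoose` terms. The odds ratio is the
  sample 2×2 odds ratio with the Haldane–Anscombe +0.5 correction on zero
  cells, flagged when applied. PRC1/PRC2 are a second, non-exclusive
  annotation layer tested alongside the mutually exclusive states.
* **LOWESS** uses span 2/3 and 3 robustness iterations (the classical
  defaults; no span is stated in the material this follows), local linear
  fits with tricube weights over the `floor(frac · n)` nearest neighbours,
  and evaluates at the distinct observed ages so curves overlay scatter
  plots directly. Trajectory correlations are computed on raw values, not
  smoothed ones.

## The pipeline and determinism

`run_scenario()` executes simulate → clean → prefilter → train → crossval →
ageaccel → ewas → enrich → assoc → trajectories, writing plain-text
artifacts and a manifest of md5 hashes. Every random draw descends from the
single configuration seed through per-stage derived seeds, so identical
configurations give bit-identical artifacts; the manifest's runtime column
is the only thing that differs between reruns. Unknown configuration keys
are errors, not warnings.

`out_of_distribution_scenario()` trains a clock on a restricted interval and
reports mean signed residuals in disjoint evaluation intervals. At generator
defaults, an unweighted clock trained on ages 40–90 underestimates simulated
centenarians by about 2 years on average (with noticeable seed-to-seed
spread, since each default cohort carries only ~16 centenarians), while the
centenarian-weighted 40+ clock removes most of that bias — the package-scale
analogue of the miscalibration that motivates centenarian clocks. The
acceptance checks average this bias over 8 replicate cohorts, a problem size
chosen to stabilize the estimate at reasonable cost.

## Problem sizes used in tests

The test suite and acceptance script run at deliberately modest scales: the
default simulated cohort (600 × 2000), smaller cohorts (150–200 samples,
300–600 CpGs) for Monte-Carlo loops over 10–20 seeds, n = 2000 for
hazard-ratio recovery, n = 344 with 2000 null CpGs for the type-I error
study, and an exhaustive hypergeometric sweep over all populations N ≤ 30.
These sizes were picked so each property is measured with adequate power
while the whole cycle stays convenient to run routinely.

## Known limitations

The elastic-net and Cox solvers are written for dense, moderate-dimensional
problems (thousands of CpGs after pre-filtering), not the full 850k-probe
scale. The neural clock is a minimal reference implementation — no
mini-batching, early stopping, or architecture search. The simulator's
independence assumptions (CpGs independent given age, exponential survival)
are conveniences, and any conclusion that depends on LD-like correlation
between CpGs, cell composition, or non-proportional hazards is outside what
this package can support.
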