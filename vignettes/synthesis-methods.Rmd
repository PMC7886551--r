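---
title: "Grouped kernel-density synthesis of clinical feature matrices: methods and design notes"
author: "synthEHR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped kernel-density synthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthEHR)
```

## The problem

Clinical feature tables carry protected health information, which makes them
hard to share and slow to analyze under the usual governance controls. A
*synthetic derivative* is a generated table that preserves the statistical
structure of an original cohort — univariate distributions, cross-feature
dependence, population-level rates — while having no one-to-one
correspondence with any real patient. synthEHR implements one complete
pipeline of this kind: a query layer that turns longitudinal event streams
into rectangular feature matrices, a synthesis engine, and a three-pronged
validation harness (distributional fidelity, train-on-synthetic/test-on-real
model evaluation, and population rate comparison).

## The synthesis model

Let $X$ be an $n \times p$ feature matrix whose columns are typed by a
`FeatureSpec` as continuous, count, binary or categorical, with a subset of
columns flagged as *grouping anchors*.

**1. Stratification ("groups of similar patients").** Rows are partitioned
into strata formed by the joint levels of the categorical anchors crossed
with per-anchor quantile bins (`nQuantileBins`, default 2) of the numeric
anchors. Strata with fewer than `minGroupSize` members (privacy threshold
$k$, default 10) are *censored in full*: their rows contribute no synthetic
observations, so row counts, inclusion tallies and extreme subgroups cannot
leak. A run in which every stratum falls below $k$ is an error, not an empty
table.

**2. Per-stratum model.** Within a stratum of size $m$ the engine fits, per
numeric dimension, a Gaussian-kernel bandwidth by Silverman's rule
$h = 0.9\,\min(s, \mathrm{IQR}/1.34)\, m^{-1/5}$ (falling back to $s$ when
the IQR is degenerate, so $h = 0$ only for truly constant columns), the
observed min/max *envelope*, the empirical level frequencies of each
categorical dimension, and the correlation matrix $R$ of the
positive-bandwidth dimensions.

**3. Sampling.** Each synthetic row starts from a single donor row drawn
uniformly from the stratum, so cross-feature dependence — including the
association between binary outcome columns and the rest of the matrix — is
inherited jointly rather than reassembled from marginals. Numeric dimensions
are then jittered with Gaussian kernel noise drawn *jointly* under $R$ and
scaled by the per-dimension bandwidths, using the variance-corrected
smoothed bootstrap: with shrink factor $c_j = (1 + h_j^2/s_j^2)^{-1/2}$,

$$x^\ast_j = \bar{x}_j + c_j\,(x^{donor}_j - \bar{x}_j) + c_j h_j
\varepsilon_j, \qquad \varepsilon \sim N(0, R).$$

Plain donor-plus-noise sampling inflates every variance by $h_j^2$ and
attenuates every correlation by roughly $1/(1+h^2/s^2)$ — about a 0.03 drop
at $n = 2000$ for $\rho = 0.8$, enough to visibly bias the correlation panel
of the fidelity report. The correction preserves within-stratum mean and
variance exactly, and with (approximately scale-proportional) Silverman
bandwidths it preserves correlation as well; simulation at $n=2000$,
$\rho=0.8$ centers the synthetic Pearson correlation at 0.800. Count
dimensions are rounded half away from zero after jittering; categorical and
binary dimensions keep the donor's level, which is exactly a draw from the
stratum's empirical joint frequency (its margins are the model's frequency
tables, so synthetic category counts track real ones up to resampling
noise).

**4. Envelope censoring.** Any jittered value outside the stratum's observed
min/max triggers a redraw of that dimension's kernel noise (up to
`maxRejects`, default 10, after which the value is clipped and the clip
counted). Synthetic values therefore never exceed the real per-stratum
range: outlying individuals cannot be reproduced, at the cost of synthetic
maxima that sit at or below the real maxima.

The number of requested draws equals the original row count, allocated to
strata in proportion to their size, so the emitted count is the input count
minus the censored rows — close to, but not exactly, $n$, which is itself a
privacy feature.

### Why grouping anchors matter

Global Silverman bandwidths on heavy-tailed or zero-inflated columns are
badly mis-scaled for the bulk of the data: the kernel noise erases point
masses (e.g. a spike at zero in a severity score) and, combined with
envelope rejection at a hard lower bound, biases the lower tail upward. Both
effects are large enough that a rank-sum test comparing a cohort with its
derivative rejects essentially always. Declaring the skewed columns as
grouping anchors localizes the bandwidths to quantile-bin strata, where
dispersion is small; synthesis then behaves like a stratified smoothed
bootstrap, and the same rank-sum comparison is indistinguishable in well
over 90% of runs. This is the practical reading of "models built on groups
of similar patients": the grouping *is* the adaptivity of the kernel.

Two quantile bins per anchor is the default because the stratum count grows
as $\text{bins}^{\#anchors}$ and strata need to stay comfortably above $k$:
three anchors at 2 bins on a 410-row cohort give 8 strata of roughly 50
rows, while 4 bins would push median stratum size below 30 and begin
censoring tails wholesale (which shows up as significant rank-sum
differences, since the synthetic table then lacks the real tails).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `minGroupSize` | 10 | privacy threshold $k$; strata below it are censored in full |
| `nQuantileBins` | 2 | quantile bins per numeric grouping anchor |
| `bandwidthRule` | `"silverman"` | per-dimension kernel bandwidth rule |
| `envelopePolicy` | `"reject-then-clip"` | treatment of out-of-envelope draws |
| `maxRejects` | 10 | noise redraws before clipping |
| `seed` | — | single integer; all synthesis randomness derives from it in a documented draw order (donor indices, then joint kernel noise, per stratum in sorted-key order) |

Missing values are a hard error by default (`naAction = "drop"` removes
incomplete rows first); the query layer, not the engine, is where
missingness is expected to be handled.

## The validation harness

**Fidelity** (`buildReport`): numeric features are compared between the real
table and its derivative with the Wilcoxon rank-sum test (exact enumeration
below a combined $n$ of 20 without ties; otherwise the tie-corrected normal
approximation without continuity correction) and the two-sample
Kolmogorov–Smirnov test, alongside a six-point quantile panel (min, 25th,
50th, 75th, 90th, max; type-7 linear interpolation). Binary and categorical
features get a chi-squared test on level counts. All $p(p-1)/2$ pairwise
correlations are compared and the maximum absolute delta flagged. No
multiple-testing adjustment is applied — the report counts tests below
$\alpha$ (default 0.05, configurable because any fixed threshold should vary
by use case) rather than adjusting them.

**Utility (TSTR)** (`runTSTRGrid`): an L2-regularized logistic regression
(glmnet ridge path at a single penalty; features standardized on the
training source only, so no leakage into test sets) is evaluated over the
three train/test cells real→real, synthetic→synthetic and synthetic→real,
each with training-split, stratified 5-fold cross-validation and 20%
stratified holdout metrics (accuracy, precision, recall, F1, AUROC; AUROC by
mid-rank statistic). The real holdout is computed once and shared by the
real→real and synthetic→real cells, so the transfer comparison is on
identical rows. For the synthetic→real cell, fold models are trained on
synthetic folds and validated on the corresponding real training folds. The
default penalty is unit-strength L2 on standardized features
($\lambda = 1/n$, i.e. total objective $\sum_i \ell_i + \tfrac12\lVert w
\rVert^2$), and the classification threshold is 0.5; neither choice is
data-driven.

**Rates** (`aggregateRates`, `rateDifference`): events are tallied per
year/zip against census denominators, rates reported per 100,000 to one
decimal, and synthetic-minus-real differences carry a Wald 95% CI with
Poisson variance $\mathrm{rate}^2/\mathrm{count}$ per arm. The sign
convention is synthetic − real. The CI construction used in the source
material for such comparisons is not derivable from its printed values, so
only point differences are checked exactly; our Wald intervals are
documented as our own choice.

## What the simulated cohorts do and do not show

Real patient-level data for the three study settings are not available, so
the package ships generators that target published *summaries*, with every
target a named parameter:

- `genTrauma`: 410 patients; a zero-inflated negative-binomial severity
  score (median 2), log-normal alarm counts (median 229) and stays (median
  1.3 days), a Gaussian copula tuned so the Spearman correlation between
  severity and alarm rate sits near 0.34 (the latent correlation equals the
  target: discretization ties attenuate ranks by about as much as the
  latent-to-rank inflation, verified by simulation), and severity/alarms/
  stay as grouping anchors.
- `genSepsis`: 643 cases and 1286 controls (prevalence exactly 1/3 by
  stratified rejection against a fixed logistic truth model on standardized
  features), 169 features by default (7 continuous vitals/demographics, the
  rest binary flags cross-correlated through a latent acuity variable);
  tests run a reduced 40-feature version for speed, and both paths are
  exercised. The truth coefficients are returned for recoverability checks.
- `genChlamydia`: six years of zip-coded events, Poisson counts at per-year
  target rates (78.5–105.5 per 100,000) against a synthetic 12-zip census
  catchment of 580,892 people, truncated-normal ages (23 ± 5.7, ≥ 13) and a
  declining female majority.

Passing tests on these cohorts show that the engine preserves the *kinds* of
structure the generators encode — heavy tails, point masses, rank
correlations, label–feature dependence, Poisson rate structure. They do not
show robustness to features of real EHR data the generators deliberately
omit: missingness, measurement artifacts, extreme-cardinality categoricals,
temporal drift, or tail shapes beyond the log-normal family (the real alarm
maximum implies a tail whose exact form is unknowable from summaries; tail
shape here is a parameter, not a claim).

## Numerical choices and degenerate inputs

- Quantile convention is type 7 (linear interpolation) throughout.
- Window endpoints in the query layer are closed on both ends; stays of
  exactly 24 h use the 12-h index rule; abnormal-flag thresholds compare
  inclusively. All three conventions are boundary choices the source
  material leaves open, fixed here and documented.
- Variance uses the $n-1$ denominator.
- Constant columns synthesize to the constant (bandwidth 0) rather than
  erroring; constant inputs to rank correlation return `NA` with a warning;
  all-tied rank-sum inputs return $p = 1$ with a degeneracy flag.
- The empirical kernel correlation matrix is eigenvalue-clipped at $10^{-8}$
  before factorization, so rank-deficient strata still sample.
- Count columns round half away from zero after jittering.
- Sub-seeds for multi-stage procedures (holdout split, fold assignment,
  synthetic split) are small fixed offsets of the user seed; all remain
  32-bit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at the study scales the
generators encode: 410-row trauma cohorts (100 replicate seeds for the
similarity property), 1929 × 40 sepsis matrices (20 replicate seeds for
transfer parity; the 169-feature default is exercised once), 2000-row
bivariate normal draws (100 seeds for the correlation/K-S bands), and
6-year × 12-zip event tables. These sizes reproduce the published settings
at full cohort scale while keeping the whole suite in the tens of seconds.

## Known limitations

- The synthesis mechanism is this package's own documented variation of
  multivariate kernel-density sampling; it is not a reimplementation of any
  proprietary engine, and no claim of mechanism-level equivalence is made.
- Derived columns (e.g. a rate defined as count/stay) are jittered as
  ordinary dimensions; the arithmetic identity between synthetic columns is
  preserved only approximately, through their joint dependence.
- Privacy guarantees are structural (no row correspondence, $k$-threshold
  stratum censoring, envelope restriction, zero exact-match assertion) —
  there is no differential-privacy accounting or formal re-identification
  risk score.
- Rate-difference CIs assume Poisson counts and independence between arms.
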