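---
title: "Multi-stressor interaction analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stressor interaction analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmix)
```

This vignette is the package's own account of the statistics it
implements: the growth endpoint, the multiplicative null model and the
interaction coefficients built on it, the two-stage bootstrap, the
phylogenetic-signal tests, what the synthetic generator does and does
not emulate, and the numerical and design choices that were genuinely
open.

## 1. Growth endpoint: spline AUC and relative growth

Each well contributes an OD time series (hourly over 0–72 h in the
emulated design). A stressor may lengthen the lag, slow growth or
lower the carrying capacity; rather than privileging one phase, the
fitness endpoint is the **area under the growth curve**. A cubic
smoothing spline is fitted per well with the smoothing parameter
chosen by generalized cross-validation (`stats::smooth.spline`); an
interpolating spline on hourly data would chase reader noise, while
the GCV spline reproduces constants and straight lines exactly
(they lie in the roughness penalty's null space) and adapts its
flexibility to the signal. The fitted spline — clamped at zero from
below, since negative OD is unphysical — is integrated segment by
segment with 5-point Gauss–Legendre rules, which are exact for cubic
polynomials, so the AUC is the integral of the fitted curve, not a
quadrature over the raw points.

Relative growth for a culture × mixture is
`G = mean(treatment AUC) / mean(control AUC)`. The control pool is all
control wells of that culture (the emulated design has 45 control
microcosms × 4 replicates = 180 wells); per-replicate pairing is not
used because controls are not paired with treatments. Uncertainty in
the control mean is propagated by resampling the control pool inside
the bootstrap, not by error formulas.

**Baseline correction** is off by default (raw absorbance); an
optional per-well subtraction of the minimum of the first three
readings is available (`plate_auc(..., baseline = TRUE)`) for plates
where media blanks matter. Both paths are supported because raw vs
blank-corrected absorbance is a genuine free choice in this kind of
analysis.

## 2. The multiplicative null and interaction coefficients

Relative growth is a percentage-scale quantity, so independent
effects must compound multiplicatively: two stressors each reducing
growth by 70 % predict a combined 1 − 0.3 × 0.3 = 91 % reduction,
whereas adding effects would predict 140 % — meaningless, since a
reduction is bounded at 100 %. All coefficients are therefore ratios
against product-form nulls:

* **Net**: `N_A = G_A / prod(G_a)` over the singletons of `A` — the
  total deviation from independence, whatever its source.
* **Emergent**: `I_A` additionally divides out every lower-order
  interaction among proper subsets of `A`, computed iteratively in
  increasing subset size (pairs, then triples, …). For `|A| = 2` the
  two coincide. The recursion telescopes to the inclusion–exclusion
  (Möbius) form `log I_A = sum over non-empty S ⊆ A of
  (−1)^(|A|−|S|) log G_S`; the package implements the iterative
  definition as the primary path and the closed form as an
  independent oracle (`mobius_log_interaction`), with equivalence to
  1e−10 in log space enforced by the test suite over random lattices.
* **Partial-order residuals**: `partial_null_residual(lattice, A, m)`
  divides `G_A` by singletons and all emergent terms of order ≤ m,
  interpolating between net (m = 1) and emergent (m = |A| − 1). The
  lower-order terms are emergent (not net) coefficients — the only
  reading under which the m = |A| − 1 case recovers `I_A`. This is
  the machinery behind the "how many interaction orders are needed"
  table (`terms_required_table`).

**Numerical choices.** All lattice arithmetic is carried in log space
and exponentiated at the end; products of up to 255 ratios would
otherwise under/overflow. Relative growths below a floor (default
`g_floor = 1e-4`) are raised to it before the log transform and the
affected mixtures flagged on the lattice object — zero-growth wells
have no defined log ratio, and flagging beats silently dropping them.
Incomplete lattices (a missing subset pool) fail loudly, naming the
missing subset, rather than imputing.

## 3. Two-stage bootstrap and classification

Stage 1 — the **gate**: for each mixture, treatment and control AUC
pools are resampled with replacement (10,000 replicates by default),
G recomputed each time, and a percentile CI formed. A CI containing 1
means the mixture did not change growth; such mixtures are classified
`no_response` and their interactions are not interpreted.

Stage 2: for gated mixtures, each bootstrap replicate independently
resamples the replicate pool of *every* subset term entering the
coefficient's formula, recomputes all lower-order coefficients from
the resampled data, and finally the target coefficient; the
percentile CI decides significance. The **shared control pool is
resampled once per replicate** and reused in every G term of that
replicate, because every G divides by the same control mean —
resampling it independently per term would overstate independence.
(Whether the original procedure resampled controls jointly or
per-term is ambiguous; the joint choice is this package's documented
assumption.) The gate and the interaction test use independent seed
substreams.

Classification is direction-aware. With the null prediction itself a
growth reduction, a ratio CI above 1 dampens the predicted effect
(**antagonism**) and below 1 amplifies it (**synergism**); with a
beneficial null the mapping flips. A null prediction of exactly 1
with a significant ratio is classified by whether the deviation
amplifies |G − 1| and logged as an edge case.

Intervals are **percentile** intervals — the minimal reading of
"bootstrap 95 % CI" — not BCa. No multiple-testing correction is
applied by default (each mixture is reported marginally); a
Benjamini–Hochberg switch exists but defaults off.

**Seed discipline.** One master seed; per-(culture, mixture, kind)
substreams are derived by hashing (`substream_seed`), so adding or
removing a mixture never perturbs another mixture's CI, and equal
seeds give byte-identical outputs end to end (enforced by tests on
the CLI).

**Floating-point tie-break.** "CI excludes 1" uses a relative
tolerance of 1e−9: on noiseless replicate pools (used heavily in
validation) a coefficient that is mathematically 1 computes to
1 ± a few ulps and must not register as an interaction. Real data are
never within 1e−9 of degeneracy.

## 4. Known limitation: percentile bootstrap at n = 4

With four replicates per pool, the bootstrap distribution of a pool
mean has only 35 support points and its variance is (n−1)/n = 3/4 of
the unbiased estimate, so percentile CIs are systematically narrow:
the CI behaves like ±1.96·(0.87·SE) rather than a t-interval. The
acceptance script measures the consequences directly on synthetic
data: singleton-G CI coverage is ≈ 80 % (not 95 %), planted pairwise
interaction coverage ≈ 85 %, and the fraction of truly multiplicative
mixtures called interacting is ≈ 13–15 % rather than 5 %. This is a
property of the prescribed procedure (percentile intervals at four
replicates), not of the implementation — a pure reference simulation
of the percentile interval for a mean of four normal values shows the
same coverage — and it is reported honestly rather than patched,
because the procedure itself (resample-with-replacement, percentile
CI, CI-excludes-1 rule) is part of the method being reproduced.
*Detection* of planted effects is unaffected at realistic noise:
strong effects and the planted antagonism are detected and typed
correctly in essentially every simulated dataset.

## 5. Phylogenetic signal

Response **fingerprints** (the 255-long G profile per culture, in the
canonical mixture order) are compared by Euclidean distance,
clustered hierarchically (average linkage by default; the linkage was
not dictated by anything in the method, so it is configurable:
average/complete/ward), and tested against patristic distances with a
one-sided **Mantel test using Kendall's τ** (`vegan::mantel`;
p = (1 + #{permuted τ ≥ observed}) / (n_perm + 1), 9,999 permutations
by default). Kendall's τ is used because phenotypic distance vectors
are far from normal. By default fingerprints use the unmasked mean-G
profile; a significance-masked variant (non-significant responses set
to 1) is available, since either reading of "the response phenotype"
is defensible.

Per-chemical scalar responses are tested with:

* **Pagel's λ** — the Brownian-motion likelihood with off-diagonal
  (shared-history) covariance entries scaled by λ, maximised on
  [0, 1] by bounded search (tolerance 1e−8), with a likelihood-ratio
  test against λ = 0 (χ², 1 df). The λ = 0 model is exactly the
  independent-tips normal likelihood with tip-height variances, which
  the tests verify in closed form. G values are left-skewed, so a
  **rank-based inverse-normal transform** (Blom offsets, ties
  averaged) is applied before the λ test: it is parameter-free,
  deterministic and monotone, but it is *a* normalising transform,
  not necessarily the one used in any particular prior analysis —
  λ values can differ across transform choices.
* **Blomberg's K** — observed MSE₀/MSE over its Brownian expectation
  on the same tree, with a randomization p-value: the proportion of
  tip-label shuffles whose GLS MSE is ≤ the observed (1,000 shuffles
  by default, +1 continuity correction so p ∈ (0, 1]). On a star tree
  with equal branch lengths K is exactly 1 for any trait (verified in
  closed form); K is affine-invariant in the trait.

Both statistics are implemented in the package (the bounded-λ
contract and caller-seeded randomization required it) and are
cross-checked in the test suite against `phytools::phylosig`, which
agrees to 1e−12 on K and to optimizer tolerance on λ.

## 6. The synthetic generator

`generator_spec()`/`simulate_plate()` emulate a full-factorial plate
experiment with known truth. Ground-truth relative growth is defined
directly on the AUC-ratio scale — the scale the analysis estimates —
via a log-linear model: `log G_A = Σ log g_a + Σ log ι_k` over planted
singleton effects `g` and interaction coefficients `ι` on chosen
subsets. Each well draws a logistic curve whose carrying capacity and
rate are both scaled by `G^θ`, with θ solved per target by a
one-dimensional root find on the closed-form logistic AUC so that the
noiseless AUC ratio equals the planted G (tolerance ~1e−12 in the
solver; the noiseless pipeline reproduces planted G to < 1e−3 through
the spline). Planting effects on the rate or capacity alone would
make true G depend on the integration window; calibrating on the
endpoint scale keeps truth and estimand identical. Unreachable
targets (a culture whose capacity would fall below its inoculum) are
refused with an error.

Noise is additive Gaussian on OD, truncated at zero
(plate-reader-like; a multiplicative lognormal option exists). The
default `noise_sd = 0.01` OD is a realistic reader scale; no
quantitative noise model was available to estimate, so this is a free
parameter chosen once. Per-well noise streams are independent
substreams of the master seed.

`paperlike_preset()` fixes the emulated study conditions: 8
chemicals, 255 mixtures + 45 control microcosms, 4 replicates (1,200
wells per culture), hourly readings over 72 h, one severe
antibiotic-like chemical (g ≈ 0.24–0.36 across cultures, which makes
the G distribution bimodal on its presence), mild effects for the
rest, a planted antagonism (ι = 2.0) between the antibiotic and a
fungicide, and 12 cultures with deterministically varied
susceptibility.

**What the generator does not emulate:** contamination events,
biofilm and condensation artifacts, lag-phase heterogeneity between
replicates, dose–response (a single concentration per chemical),
plate-position effects, and community dynamics (a mixed culture is
just another "culture" with its own response profile). Passing tests
on synthetic data therefore validate the *statistical machinery* —
estimation, calibration, classification, recovery — not the biology
of any particular dataset.

## 7. Validation problem sizes

The test suite and `scripts/acceptance.R` use: 200 random lattices
(panels of 2–8 chemicals) for the oracle-equivalence check; 100
simulated preset datasets (one culture each, bootstrap B = 1,000) for
recovery and coverage; six independent purely-multiplicative cultures
(8 chemicals, 4 replicates, B = 1,000; 1,482 interaction tests) for
the type-I rate; 500 simulations each for Mantel and Blomberg null
calibration (199 permutations/shuffles) and for Brownian recovery of
λ and K on a 64-tip coalescent tree. These sizes give Monte-Carlo
standard errors well inside the asserted bands while keeping a full
validation run to a few minutes on one CPU; B = 1,000 rather than the
production default of 10,000 does not affect coverage or type-I
rates, only CI quantile smoothness.

## 8. Other design decisions

* Chemicals are referenced **by name** in data files; the panel file
  fixes the canonical order, and subsets are encoded internally as
  bitmasks over panel indices for O(1) lattice operations.
* All tabular I/O is plain delimited text (comma default, tab
  auto-detected); plate-reader vendor formats are out of scope.
* Contamination handling: an explicit exclusion list on read
  (`read_plate_table(..., exclude_wells = )`), recorded on the
  returned object; no automatic heuristic is applied unless asked.
* `response_sign_table` classifies responses by the **gate CI**
  (negative = CI entirely below 1), not by the point estimate's sign,
  so "no response" is an explicit category.
* The complexity regression (`complexity_regression`) is ordinary
  least squares of per-mixture mean G on complexity and a focal
  chemical indicator, pooled across cultures by default with a
  per-culture option — mixture means, not replicate-level values, are
  the regression points.
* Zero-length tree branches are replaced by a configurable epsilon on
  read (logged), since the signal statistics require positive branch
  lengths.
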