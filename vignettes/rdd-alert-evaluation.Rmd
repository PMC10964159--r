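---
title: "Methods: regression discontinuity evaluation of a deterioration alert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression discontinuity evaluation of a deterioration alert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddalert)
```

## The design

A ward deterioration index between 0.0 and 100.0 is recomputed throughout
each hospitalization; when it first reaches the threshold `c = 65.0` the
care team is alerted. Each hospitalization contributes one running-variable
value: the maximum score, censored at the time of the first event (rapid
response team activation, ICU transfer, cardiopulmonary arrest, or
inpatient death), so that post-event scores cannot contaminate the running
variable. Treatment assignment is the deterministic step `D = 1{X >= c}`
(a score exactly at the threshold triggers the alert, so `X = c` belongs to
the treated side throughout the package).

The estimand is the local average effect of the alert at the threshold,

$$\tau \;=\; \lim_{x \downarrow c} E[Y \mid X = x] \;-\;
\lim_{x \uparrow c} E[Y \mid X = x],$$

identified under two assumptions that the falsification suite probes
directly: (i) the density of `X` is continuous at `c` (nobody sorts scores
across the threshold), and (ii) all confounders are continuous at `c`.

Patients with silent (test) alerts or comfort-care orders may carry the
assignment without receiving the intervention. Following intention-to-treat
logic, such records stay in the analysis under `D = 1{X >= c}`; the
generator models them through `contamination_rate`, and the estimated jump
then attenuates toward `(1 - contamination_rate) * tau`, which the
assignment-discontinuity check makes visible as a treated-fraction jump
below 1.

## Estimation

`rd_estimate()` fits weighted least squares of the outcome on the centered
basis `(X - c)^0..p` separately on each side, with kernel weights
`K((X - c)/h)`; the side intercepts are the two one-sided limits and their
difference is `tau_hat`. Defaults: triangular kernel (linearly declining
weight, zero at distance `h`, support open at `|X - c| = h`), local linear
(`p = 1`), with local quadratic (`p = 2`) used as a specification check in
the pipeline.

**Inference.** The variance of each intercept is heteroskedasticity-robust
(HC1-type sandwich on the weighted fit). Binary outcomes are
heteroskedastic by construction, and robust variances are the default
throughout the RD literature; a homoskedastic `vce = "ols"` option exists
for closed-form oracle comparisons in the tests. Confidence intervals and
two-sided p-values are normal-based with no t-correction: in-bandwidth
sample sizes are in the hundreds, where the difference is negligible; this
choice is deliberate and documented rather than silently version-dependent.
Conventional (not bias-corrected) local-polynomial inference is reported —
the convention matched by pairing an MSE-optimal bandwidth with the plain
local fit. Estimates are stored in native units; printing and table
formatting convert binary outcomes to percentage points (covariates stay in
years, index points, days).

**Units and sides.** `n_left`/`n_right` count records with strictly
positive kernel weight; a fit requires at least `p + 2` such records per
side and errors otherwise, naming the side and the count.

## Bandwidth selection

`cct_bandwidth()` implements a plug-in MSE-optimal selector in the
Calonico–Cattaneo–Titiunik style, returning the single symmetric `h`
minimizing the asymptotic MSE of the discontinuity estimator:

$$h = \left( \frac{V}{2(p+1)\,(B^2 + R)\,n} \right)^{1/(2p+3)},$$

with variance constant `V = v_K (sigma^2_+ + sigma^2_-) / f(c)` and bias
constant `B = b_K\,(m^{(p+1)}_+ - (-1)^{p+1} m^{(p+1)}_-)/(p+1)!`. The
boundary kernel constants `b_K`, `v_K` are computed exactly from rational
one-sided kernel moments (for the triangular kernel at `p = 1` they are
−1/10 and 24/5 — the same constants that appear in the published density
test's variance formula, which doubles as a check on the derivation).

Pilot quantities, each chosen for determinism and scale equivariance:

* `f(c)`: Gaussian kernel density estimate with Silverman's rule-of-thumb
  bandwidth;
* `sigma^2_±(c)`: residual variance of side-wise local linear fits in a
  uniform pilot window `1.84\,\mathrm{sd}(X)\,n^{-1/5}` (widened to the
  five nearest points if too narrow);
* `m^{(p+1)}_±(c)`: the degree-`p+1` coefficient of global side-wise
  polynomial fits of order `p + 2`, solved on a standardized basis so the
  selector stays well conditioned under affine rescaling of the score.

The regularization term `R = 3(V_{B+} + V_{B-})` (three times the variance
of the estimated bias constant) is **on** by default. Two consequences
worth understanding:

* the selector is exactly equivariant under affine maps of the score
  (`h` scales with the score units and is shift-invariant), which the
  tests assert to 1e-6;
* when the true curvature difference at the cutoff is near zero — as it is
  for this package's default, nearly-linear-at-the-threshold outcome curve
  — `R` dominates `B^2` and `h` plateaus in `n` instead of shrinking like
  `n^{-1/(2p+3)}`. That is the regularization doing its job (preventing
  `h → ∞`), not a defect; the asymptotic-rate test therefore uses a
  covariate with strong one-sided curvature, where the MSE optimum is
  interior.

No independently maintained implementation of this selector is installable
in the build environment, so the cross-implementation oracle in the tests
is a synthetic stand-in: a second implementation of the same published
formulas, written independently in numpy, evaluated once on three seeded
fixtures, with the resulting bandwidths frozen as constants (agreement
achieved: identical to ~10 significant digits; the test asserts the
spec-level 5%).

## The McCrary sorting test

`mccrary_test()` follows the published two-stage recipe. First stage: an
undersmoothed histogram with automatic bin size `b = 2\,\mathrm{sd}(X)
n^{-1/2}`, the cutoff sitting exactly on a bin edge (so no bin straddles
`c`; a score equal to `c` counts to the right, consistent with
assignment). Second stage: triangular-kernel local linear fits of the
normalized bin heights on bin centers, separately on each side, evaluated
at `c`. The statistic is `theta = log f_+(c) - log f_-(c)` with asymptotic
standard error `sqrt((24/5)(1/f_+ + 1/f_-)/(n h))` and a two-sided normal
p-value. The automatic smoothing bandwidth uses the published rule — global
quartic fits of the bin heights per side, `h = 3.348\,(\hat\sigma^2
\cdot \mathrm{range} / \sum \hat f''(x_j)^2)^{1/5}`, averaged over sides —
capped at the side's span so an exactly-flat density cannot push `h` to
infinity. Both tuning constants can be overridden, and the realized values
are recorded in the result, since no published deployment of this analysis
states which constants it used.

## The synthetic world

`generate_cohort()` states one world and the tests measure the estimators
inside it:

* **Scores**: `100 * Beta(1.6, 3.15)` rounded to a 0.1 grain — right-skewed,
  bounded, mean ≈ 34 — with the second shape parameter solved so that
  `P(X >= 65) = 771/9896 ≈ 7.8%`, the above-threshold fraction of the
  deployment this design models. Real maximum-score distributions have
  additional structure (mass near round numbers, unit-specific mixtures)
  that a two-parameter Beta does not emulate.
* **Primary outcome**: `P(escalation) = plogis(qlogis(0.35) +
  0.04 (X - c)) + tau · 1{X >= c, not contaminated}`, with default
  `tau = -0.104`. The intercept and slope put in-bandwidth event rates in
  the 20–50% range a deterioration-alert cohort plausibly shows; they were
  fixed once, before any calibration test was run, and define (not chase)
  the power of every downstream check. Conditional on an escalation, the
  component flags are drawn with ICU transfer most likely and arrest rare,
  with at least one flag guaranteed.
* **Death** follows its own smooth logistic curve with zero jump by
  default, so the secondary composite (escalation or death) shows an
  attenuated effect, and the death row of the results table is a built-in
  negative control. A death jump is configurable.
* **Covariates** (age, Elixhauser index clamped to [−19, 89] and rounded to
  integers, days to maximum score) are linear in `X` plus Gaussian noise —
  smooth through the threshold by construction, giving the balance checks a
  true null. `missing_covariate_rate` masks age and comorbidity jointly,
  mimicking registry missingness.
* **Seeding**: one master seed, split into named sub-streams (scores,
  outcomes, components, death, each covariate, contamination, missingness,
  manipulation) via a fixed label hash, so adding a covariate or toggling
  contamination cannot perturb the score draws.

`simulate_trajectory_max()` exists to make the censoring story concrete: a
latent peak severity is drawn from the same score distribution, the
trajectory is the peak minus the absolute excursion of a Gaussian random
walk (bounded in [0, 100], attaining its peak exactly once), and a per-step
event hazard increasing in the current score censors the recorded maximum
at the event. With zero hazard the recorded maximum equals the latent peak,
so its distribution matches `generate_cohort()` exactly — which is what the
distribution-matching test checks; with positive hazard, censoring pulls
maxima down. It is a qualitative device, not a calibrated model of
15-minute score dynamics.

**What a green test establishes.** Calibration and power statements hold in
this stated world: smooth logistic risk, exact Beta scores, exogenous
covariates. They do not establish performance under features the generator
omits — discrete bunching at score round-offs, unit-level heterogeneity,
time-varying thresholds, or informative missingness.

## Numerical and design choices

* A record at `X = c` is treated/above everywhere (assignment, binning,
  histograms); kernel support is open at `|X - c| = h`.
* `inject_manipulation()` relocates scores and then recomputes the
  assignment-derived `treated` flag from the new scores — manipulation
  happens *before* assignment, as it would in reality — leaving outcomes
  and covariates untouched. It is a density-test power tool; a cohort it
  produces is deliberately incoherent (outcomes were drawn under the old
  scores).
* The mislabeled-placebo sanity check: with `tau = -0.104` at
  `n = 10{,}000` and the default event rates, the placebo check's power is
  ≈ 0.5 (|tau|/se ≈ 2), so the test asserts detection at many times the 5%
  null rate rather than a knife-edge majority.
* Side-specific bandwidths are not offered: the design being modeled
  reports a single symmetric bandwidth per analysis, and the pipeline
  recomputes that bandwidth independently per outcome (which is why each
  results-table row carries its own `h`).
* Sensitivity sweeps vary `h` only, holding kernel, order, and variance
  estimator fixed; this is recorded in the sweep object itself.
* The formatted results table rounds estimates/CIs to 1 decimal (percentage
  points) and bandwidths to 2; the machine-readable CSV keeps full
  precision. PDFs embed timestamps, so byte-identity across same-seed runs
  is guaranteed for (and asserted on) the machine-readable outputs.
* Records with a missing outcome are dropped from that fit with a logged
  count; covariate missingness removes records only from that covariate's
  balance fit. Which convention a real deployment used for its in-bandwidth
  patient count is not recoverable from published tables alone (two counts
  differing by exactly the in-bandwidth missingness appear), and the
  generator can reproduce either via `missing_covariate_rate`.

## Known limitations

* Conventional (not robust bias-corrected) CIs: undercoverage can appear if
  the MSE-optimal bandwidth is paired with strongly curved outcome
  surfaces; the recovery test's coverage band is the empirical check.
* The density test's asymptotic SE is known to be slightly conservative or
  liberal depending on binning at moderate `n`; the suite constrains its
  size to [0.03, 0.08] rather than exact nominal.
* The generator draws independent hospitalizations; no within-unit or
  within-period correlation, no stepped-wedge rollout structure (units and
  periods are labels only, by scope).
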