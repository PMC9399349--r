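---
title: "Estimating daily milk yield from single AM or PM milkings: models, evaluation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating daily milk yield from single AM or PM milkings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmyield)
```

## The estimation problem

Under an AM–PM milk-recording plan a cow is milked twice on a test day
but only one milking — the morning (AM) or the evening (PM), alternating
across test days — is weighed. The recorded quantity is a single-session
yield `x` (kg) together with its milking interval `t` (hours since the
previous milking), the cow's days in milk `d`, and covariates such as
parity and lactation month. The target is the daily milk yield
`y = x_AM + x_PM`.

If both intervals were exactly 12 h and secretion were uniform, `y = 2x`
would be exact. In recorded data AM intervals are systematically longer
than PM intervals (the two must sum to roughly 24 h), so `2x`
over-estimates daily yield from AM milkings and under-estimates it from
PM milkings. Every estimator in this package is a different way of
correcting that bias; all share the covariates `(x, t, d)` and a session
label `j ∈ {AM, PM}`.

Two prediction strategies run through the suite. A *direct* ("A")
strategy plugs the record's exact `t` and `d` into the fitted equation.
A *factor* ("B") strategy first discretizes the interval axis into
milking-interval classes (MICs) and tabulates one correction per class,
evaluated at the class midpoint `t̄_j(k)`; prediction then looks up the
record's class. Factor tables are the traditional deliverable of
milk-recording organizations, but the discretization discards
within-class interval variation, so a B variant is never expected to
beat its A counterpart.

## The estimators

**M0 (doubling).** `ŷ = 2x`. The benchmark.

**M1 (categorical ACF).** The additive correction is the expected value
of `z = y − 2x` (equivalently: the complementary-session yield minus
the measured one), tabulated per session × MIC × lactation-month cell.
We estimate each cell by its training mean: in a saturated two-way
layout the sum of fitted main and interaction effects *is* the cell
mean, so nothing is gained by an explicit ANOVA solve, and the direct
mean makes the model's well-known sparse-cell instability visible
rather than hiding it behind a constrained parameterization. Empty
cells are imputed from the session × MIC marginal mean (or the session
mean if the whole class is empty) and flagged `imputed`; they are never
silently zero.

**M2 (continuous ACF).** `z = α_j + β t + γ(d − d0) + ε` by ordinary
least squares, `b = 2` fixed by construction. Prediction adds `2x`. The
factor version evaluates `Δ_j(k) = α̂_j + β̂ t̄_j(k)` at midpoints and
applies the residual DIM adjustment `γ̂(d − d0)` at prediction time.

**M3/M4 (linear regression).** `y = α_j + β t + γ(d − d0) + b x + ε`
with `b` free (M4 adds quadratic interval and DIM terms and admits no
factor strategy). M3 with `b` constrained to 2 reproduces M2 exactly —
this equivalence is asserted in the test suite via an offset
regression, and it explains why the regression models out-predict the
classical ACF models: they estimate the multiplier (typically ≈1.75 on
data like these) instead of fixing it at 2.

**M5 (bulk-proportion MCF).** Per session and class, the bulk
proportion `P_j(k) = Σx / Σy` over the class's records; a quadratic
least-squares fit of `P_j(k)` on midpoints; factors
`F_j(k) = 1/(α̂_j + β̂_1 t̄ + β̂_2 t̄²)`. AM and PM are fitted directly
and separately from their own data. The smoothing is unweighted by
default (bin-count weighting is an option) because the construction is
defined on the per-class proportions themselves, not on records.

**M6 (per-class no-intercept regression).** Within each session ×
class, `y = b_jk x + γ_jk (d − d0) + ε` without intercept; the
reciprocals `1/b̂_jk` are smoothed linearly on midpoints,
`F_j(k) = 1/(α̂_j + β̂_j t̄_j(k))`; prediction applies the per-class DIM
slope additively. Classes with fewer than two records, or with zero
`Σx²`, are skipped and marked; the smoothing line needs at least two
populated classes.

**M7 (ratio regression).** `x/y = α_j + β t + γ(d − d0) + ε`. Direct
prediction is `ŷ = x/(α̂_j + β̂ t + γ̂(d − d0))`; a non-positive
denominator is an error naming the offending record, never a silent
negative estimate. The factor version takes local expectations
(first-order Taylor step `E(x/y) ≈ E(x)/E(y)`), giving
`F_j(k) = 1/(α̂_j + β̂ t̄_j(k))` with positivity enforced over the grid.

**M8 (exponential regression).** `y = x^b e^{α_j + β t + γ(d − d0) + ε}`
with multiplicative lognormal error, fitted by OLS on the natural-log
scale. The factor version computes, per populated class, the
lognormal-moment correction
`ρ_j(k) = exp(½(V(y)/E(y)² − b V(x)/E(x)²))` from training moments and
`F_j(k) = E(x)^{b−1} ρ_j(k) e^{α̂_j + β̂ t̄_j(k)}`; prediction multiplies
by `e^{γ̂(d − d0)}`. Classes with a single record have undefined
variance and are treated as unpopulated: they borrow the nearest
populated class's moments and are flagged.

All joint fits stack each training record's AM and PM rows with
session-specific intercepts and common slopes; separate fits refit
everything per session. Training always uses fully paired records (both
yields known — this is how correction factors are derived in practice),
while prediction uses only the measured session.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| MIC bin width | 1 | h | hourly classes are the conventional factor-table resolution |
| MIC grid span | 6–20 | h | covers the observed interval range; sparse tails fall into terminal bins |
| `d0` | 158 | days | mid-lactation reference; only shifts intercepts |
| folds `k` | 10 | — | standard choice; each record tested once per replicate |
| replicates | 30 | — | stabilizes the variance component of the decomposition |
| fold unit | record | — | cow-level folding available to prevent same-cow leakage |
| `σ²` | full-data variance of `y` | kg² | see "Numerical choices" |
| spline selection | GCV | — | needs no distributional machinery; REML available |

Out-of-grid intervals are clamped to the terminal class and flagged
rather than dropped: smoothed factor tables extrapolate gracefully, and
discarding records would silently change the evaluated population.

The default grid (6–20 h, width 1) has class midpoints at half-hours.
Statements about "the 12-h class" (e.g. that multiplicative factors are
≈2 there) refer to a class whose *midpoint* is 12 h; for those analyses
an integer-centred grid (5.5–19.5 h) is passed explicitly, as in
`scripts/acceptance.R`.

## The synthetic generator

The motivating milk-recording data are access-restricted, so the
package generates paired AM/PM test-day records with the structure such
data exhibit:

* **Intervals.** `t_AM` from a normal distribution truncated to
  (6, 20) h; `t_PM = 24 − t_AM` plus N(0, 0.15 h) recording noise, so
  pairs sum to ≈24 h rather than exactly (as measured intervals do).
  The Holstein profile centres AM at 12.34 h, giving a mean AM−PM gap
  of ≈0.69 h; the Jersey profile at 12.95 h (gap ≈1.9 h).
* **Daily yield.** Linear in DIM around `d0` (slope −0.02 kg/day) plus
  a N(0, 4 kg) cow effect, times a mean-corrected lognormal residual
  (CV 8%) — multiplicative noise keeps yields positive, which M8's log
  transform requires. A Wood lactation curve `a·d^b·e^{−cd}` (rescaled
  through the `d0` anchor) is available instead of the linear form.
* **Session split.** Udder accumulation saturates as
  `g(t) = 1 − e^{−t/τ}` with `τ = 30` h; the AM share
  `p = g(t_AM)/(g(t_AM) + g(t_PM))` is jittered on the logit scale
  (sd 0.08) and the two session yields always sum exactly to the daily
  total. Saturation is what makes yield nonlinear in interval, so that
  the estimators genuinely differ; `τ → ∞` recovers the proportional
  split.
* **Covariates.** Parities ≈35/64/1% for 1/2/3+; test days ≈30 days
  apart; the measured session alternates across a cow's records as in
  an alternating plan, while the full pair is retained as evaluation
  ground truth.

What the generator does *not* emulate: day/night differences in
secretion rate beyond interval length (so its AM−PM yield gap, ≈0.7 kg
for the Holstein profile, is smaller than gaps reported for field
data), herd and seasonal effects, 3×-milking schemes, and milk
components. Passing tests therefore demonstrate correctness of the
estimators and the evaluation machinery under a controlled,
structurally faithful population — not field-data performance levels.

## Evaluation machinery

Each replicate partitions the records into `k` folds; every model is
refitted on each training split — including its MIC statistics and
factor tables, so nothing leaks from the held-out fold — and each
record is estimated exactly once per replicate. Per-replicate metrics
pool the k test folds (equivalent to the replicate-wide test error).
Across replicates the MSE decomposes as

    MSE = (1/nm) Σ_i Σ_r (ŷ_ir − ȳ̂_i)²  +  (1/n) Σ_i (ȳ̂_i − y_i)²
        =        Var                     +        Bias²

with the identity asserted at 1e-8 relative tolerance on every run; the
squared bias uses the replicate-mean estimate per record. Accuracy is
`R² = σ²/(σ² + MSE)`, which unlike a squared correlation penalizes
bias. Per-animal accuracies use each record's replicate-averaged MSE.
Paired comparisons between models are t-tests on per-replicate (or
per-record) accuracy differences; zero-variance differences are
reported as degenerate rather than raising an error.

`σ²` is defined as the sample variance of actual daily yield over the
full dataset. The alternative — recomputing it per test fold — changes
only the scaling of `R²`, not model rankings, and makes accuracies
non-comparable across folds; the definition is nevertheless exposed as
a setting (`sigma2` argument).

## Numerical choices

* **Sign of the ACF response.** `z = x_other − x_measured = y − 2x`,
  so that `ŷ = Δ + 2x` is unbiased in expectation by construction. The
  verbal definition "difference between AM and PM yield" is
  direction-ambiguous; this reading makes the prediction identity hold.
* **Singularity rule.** Aliased interval or DIM columns (e.g. constant
  `t` in a separate fit) get coefficient 0; an aliased session
  intercept or yield coefficient is an error. This keeps degenerate but
  answerable designs answerable while refusing unidentifiable ones.
* **ACF table convention.** The default `Δ_j(k) = α̂_j + β̂ t̄_j(k)`
  carries no DIM term inside the table (the residual `γ̂(d − d0)` is
  applied at prediction). A variant adding
  `γ̂(mean training DIM in class − d0)` to the table exists as a switch
  (`convention = "with_dim"`); the two coincide when class-mean DIM
  equals `d0`. Both are implemented because the two printed
  formulations of the tabulated factor disagree; neither is silently
  chosen.
* **M7B's DIM adjustment** applies the ratio-scale `γ̂` as an additive
  kg-scale term, following the published construction literally; it is
  dimensionally questionable (the slope is on the proportion scale) and
  can be switched off (`m7_dim_adjust = FALSE`). With the default
  profiles `γ̂` is ~1e-5, so the term is numerically negligible either
  way.
* **`d0(k)`** in the factor-strategy DIM adjustments is the global
  `d0 = 158`; per-class mean-DIM centring is available via the
  `with_dim` table convention.
* **Natural logarithms** throughout M8.
* **Empty classes** always receive a value from the model's own
  smoothing function (M5/M6/M7B have one by construction; M8B borrows
  nearest-class moments) and are always flagged `imputed`.
* **Model-implied yield curves** average predictions over the empirical
  local `(x, d)` distribution within the MIC window around each
  evaluation interval. This keeps the doubling model's curve equal to
  twice the local mean measured yield, making its comparison against
  the smoothing-spline mean of actual yields well-defined. Global-mean
  plug-in is available (`average = "global"`). Curves are never
  extrapolated outside the observed interval range.
* **Splines.** GCV-selected cubic smoothing splines by default; REML
  uses a cubic penalized regression spline. Fixed `λ → 0` approaches
  interpolation, `λ → ∞` the straight-line fit; both limits are
  asserted in the tests.

## Problem sizes used by the tests

The test suite exercises the machinery at sizes chosen to make
stochastic properties sharp while keeping the default run quick:
calibration checks at 10,000–100,000 draws, factor-behaviour checks at
4,000–50,000 records, parameter-recovery for the exponential model at
20 replicates of 10,000 records, and cross-validation properties at a
few hundred to 6,000 records with 5×2 to 10×5 plans. The full 10×30
plan is the package default for analyses; reduced plans in tests change
only Monte-Carlo precision, not the properties being asserted.

## Known limitations

* Strictly 2×-milking; the record types would extend to 3× plans but
  no 3× logic is implemented.
* No lactation-record (305-d) aggregation and no fat/protein
  components.
* M1 supports session × MIC × lactation-month cells only; wider
  cross-classifications (the cell count utility `acf_cell_count()`
  shows how quickly they explode) are deliberately not fitted.
* The indirect derivation of AM factors from PM factors, factor tables
  from M4, and log-scale ACF from M8 are out of scope.
* Generator realism is structural, not phenomenological: absolute
  accuracy levels obtained on synthetic data do not transfer to field
  data, though model *orderings* driven by interval asymmetry do.
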