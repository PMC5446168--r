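---
title: "Modelling temperature-drought interactions in crop yield variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-drought interactions in crop yield variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldclim)
```

## The problem

Crop yields vary from year to year with the weather. Two complications
make the climate signal hard to read off regional yield statistics.
First, both yields and climate carry strong long-term trends (breeding,
management, warming) that would induce spurious correlations if left in
place; the object of interest is the *variability* around those trends.
Second, temperature and water availability do not act additively: a hot
year hurts far more when it is also dry. `yieldclim` implements a
pipeline that takes regional production panels and gridded monthly
climate to quantile-conditioned percent-yield-change estimates with
confidence intervals, with every stage testable against synthetic data of
known structure.

## From grids and tables to anomalies

**Yields.** Yield is production divided by harvested area (t/ha). Two
quality filters guard against artefacts of self-reported statistics:
series in which the *same* production value is reported for two or more
consecutive years are truncated to the longer of the segments strictly
before the first, or strictly after the last, such run (carried-forward
reporting); and a manual exclusion list removes isolated implausible
values. Filters only ever drop rows — retained values are never altered —
and every decision is logged. Series shorter than 20 years (configurable)
are flagged unusable.

**Growing-season climate.** Monthly temperature and 1-month SPEI on a
grid are averaged over the months between planting and harvest from a
crop calendar — every month containing any day of the season counts
whole, so a March-2 planting and September-23 harvest average March
through September. Cross-year seasons are attributed to the harvest year
(yield statistics are reported for harvest years). Wheat uses the four
months ending at the harvest month, since the crop is dormant and largely
climate-insensitive over winter. Cell values are aggregated to
crop-area-weighted region means; when cells are missing, weights are
renormalized over the available ones (unbiased under missing-at-random)
with a warning once more than 25% of the weight mass is gone. Rice's two
seasons are season-weight averaged; maize uses its main season only.

**Detrending.** The log is taken first (climate acts on yields
relatively, not absolutely), then a penalized cubic regression spline of
year is removed per series. The maximum basis dimension for yields is
`max(3, floor(n/10))`, doubled for series flagged as poorly fit (a
configurable list; an automatic lag-1 residual-autocorrelation warning is
emitted but never auto-applied). Climate series use a maximum basis
dimension of 5. The spline basis can be penalized all the way to a
constant, so trendless series lose (almost) nothing. Smoothing is chosen
by GCV with an effective-degrees-of-freedom inflation factor of
`gamma = 2`: plain GCV is prone to occasional severe undersmoothing, and
for a *detrender* that failure mode is the worst possible one — an
undersmoothed trend absorbs precisely the interannual variability under
study. With this setting, pure-noise series shrink to essentially
constant trends (total edf at or near 1) in well over 90% of cases while
smooth trends of realistic amplitude are recovered essentially always.
One consequence, accepted deliberately: because the shrinkage penalty
also acts on the linear basis direction, adding a linear-in-year shift to
a climate series perturbs its anomalies slightly (a few percent of the
anomaly sd) instead of exactly zero; a basis with an unpenalized linear
nullspace would be exactly invariant but could never shrink below two
effective degrees of freedom.

## The hierarchical model

With `dT`, `dS` the current-year anomalies and `lagT`, `lagS` the
previous-year ones, the design has 13 terms: intercept; `dT`, `dT²`,
`dS`, `dS²`; the interactions `dT·dS`, `dT²·dS`, `dT·dS²`, `dT²·dS²`;
and the intensification block `lagT`, `lagS`, `lagT·dT`, `lagS·dS`.
Rows with undefined lags (each series' first year, or years after a gap)
are dropped rather than imputed — the lag terms are simply undefined
there. The model for region *c*, year *t* is

$$y_{c,t} = x_{c,t}'(\beta + b_c) + \epsilon_{c,t},\qquad
  b_c \sim N(0, \mathrm{diag}(\sigma_1^2,\dots,\sigma_q^2)),\qquad
  \mathrm{Var}(\epsilon_{c,t}) = \sigma^2\phi_c,\ \phi_1 = 1,$$

i.e. every fixed effect has a matching per-region random slope with
diagonal covariance, and residual variances differ by region through the
ratios $\phi_c$.

**Estimation.** The likelihood is evaluated per region block using the
Woodbury identity on the sufficient statistics $X_c'X_c$, $X_c'y_c$,
$y_c'y_c$, so a full evaluation costs $O(C q^3)$ regardless of the
number of years. Random-effect variances are parameterized relative to
$\sigma^2$, which lets both $\beta$ (generalized least squares) and
$\sigma^2$ profile out in closed form; the optimizer (nlminb, compiled
objective) works on the log relative variances and log ratios with
bounds at $\pm 30$ (a clamped boundary is flagged). ML is the default so
that likelihoods and BIC remain comparable across fixed-effect
structures during elimination; REML is available. Convergence is
declared on a clean optimizer exit or a numeric gradient norm below
1e-3; a multi-start option (3 deterministic starts) exists for flat
likelihoods. With 13 random-effect variances and ~54 observations per
region, the random part is weakly identified — which is why elimination
removes the fixed and random parts of a term *together*, keeping the two
structures in step.

**Inference and selection.** Wald tests use the large-sample
normal/chi-square reference for the mixed model; single-region OLS fits
(the "country" models, same 13 terms, no random effects) use the exact
classical t/F reference, which matters at n of 23-54. Backward
elimination removes, at each step, the least significant removable term
with p above 0.05, where a term is removable only if no retained
higher-order term contains it (marginality, decided on the exponent
table of the 13 terms); ties go to the higher polynomial order. Country
models are selected by greedy minimum-BIC: the least significant
removable term is proposed and the removal accepted while BIC decreases
(a BIC-ordered variant is available behind a flag). BIC counts active
fixed effects plus active variance parameters, with n the rows entering
the fit.

**Effects.** Percent effects are $100(\exp(\eta) - 1)$ with $\eta$ the
fitted log-scale effect, intercept excluded, so the all-zero anomaly
point is 0% by construction — effects are relative to the trend
expectation at average climate. `effect_at()` evaluates the full surface
at a joint climate state (used for "hot and dry" style numbers, which
include the pure conditioning-variable terms). `effect_curve()` shows
the response to one variable over its 0.05-0.95 quantile range with a
conditioning variable pinned at an empirical quantile (type-7
interpolation, pooled for global curves, per-region for region curves);
the conditioning value enters *only through interaction terms with x*,
so additive models display one identical curve at every quantile and
conditioned curves coincide at x = 0, matching how interaction figures
are read. Lags are pinned at zero except in intensification curves,
where the lag is the conditioning variable. Pointwise bands use the
delta method with the 1.96 normal multiplier; global curves exclude BLUP
contributions (they describe the global mean response; per-region curves
come from the single-region fits).

## Validation machinery

**LOOCV.** The active mask is fixed before cross-validation; no
re-selection inside folds. For the mixed model each fold re-estimates
the fixed effects and the held-out region's BLUP from the remaining
data, with variance parameters frozen at their full-data ML values by
default (re-estimating them per fold costs roughly n times more and is
available via a flag); prediction uses fixed effects plus the region's
BLUP. Folds that would reduce a region below 3 rows are skipped and
counted. The nested comparison fits Full (backward-eliminated from all
13 terms), NoInter (eliminated from the design without interaction
columns) and OnlyLin (intercept + the four linear terms); when a simpler
variant selects the same terms as the richer one, its cells are left
empty.

**Noise simulation.** Measurement error in reported yields inflates
p-values without biasing coefficients. Per series, noise with sd equal
to a fraction (1-50%) of that series' own sd is added to the detrended
log yields (same relative error everywhere; no re-detrending), the
*original* model is refit without re-selection, and the p-value of the
highest-order retained term group (interaction order beats quadratic
beats linear; joint Wald test for multi-term groups) is recorded over
100 replications per fraction, with sub-seeds derived deterministically
from the master seed. Summaries are the shares of p in the bands >0.1,
0.05-0.1, 0.01-0.05, <=0.01 per fraction. One subtlety: conditional on a
single clean dataset the null-term rejection share is *not* the type-I
rate — it reflects that dataset's chance correlation. Size checks in the
tests therefore draw fresh data per replication, while the simulation
itself keeps the conditional design.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with known truth written separately (a `.truth.json` never read by the
pipeline path): gridded monthly temperature (cell climatology + seasonal
sinusoid + linear warming of 0.25 °C/decade + shared region-year
anomalies of sd 0.6 °C + month noise) and SPEI whose per-cell-month
marginal is exactly standard normal (a shared region-year component and
independent cell-month noise with variances summing to one; optional
AR(1) in the shared component as a stress-test, independent years by
default); crop calendars and area weights; and production/area tables
built from log yields = region baseline + trend + design ×
(global + region coefficients) + heteroscedastic noise. The default
yield trend is a smooth saturating curve of amplitude 0.5 in log space
(green-revolution-like gains, deliberately nonlinear to exercise the
spline detrender); residual sd defaults to 0.08 with variance ratios
drawn in [0.5, 2]; default sensitivities are
β = (0, −0.02, −0.01, 0.03, −0.005, −0.015) on
(intercept, dT, dT², dS, dS², dT·dS) with random-slope sds of half the
absolute coefficient (0.02 for the intercept). Parameter-recovery
studies use standardized (unit-variance) anomalies, matching the
per-unit-anomaly scale on which those coefficients are defined; the
0.6 °C figure is the climate-grid realism default. What the generator
does *not* emulate — real spatial autocorrelation of climate grids,
irrigation, pests, price and policy shocks, non-Gaussian yield shocks —
bounds what passing tests show: they establish that the pipeline
recovers the structure it assumes, not that real yields obey that
structure.

## Numerical choices and degenerate inputs

Variance parameters are clamped at exp(±30) with a boundary flag; a
constant series short-circuits the spline fit (exact zero residuals);
`k >= n` spline requests, singular designs (diagnosed by column name),
rank-deficient country fits, regions below the minimum usable length,
and intercept-only masks passed to the highest-order-term rule are all
rejected with informative errors. Exact-equality is used for the
repeated-production rule (no tolerance is defensible for reported
integers); ties between the before/after segments keep the more recent
one. LOOCV and the elimination trace are deterministic and invariant to
row order; the full pipeline run twice with one seed writes
byte-identical CSVs.

## Problem sizes used in the checks

The test-suite simulations use 25 regions × 54 years for recovery and
LOOCV discrimination (100 datasets each), 200 seeds for the detrending
properties, and a 10-level noise grid with 100 replications; the
likelihood oracle is checked against a brute-force joint Gaussian
density on all instances up to 5 regions × 10 years at 1e-8. These sizes
give Monte-Carlo errors comfortably inside the asserted bounds while
keeping a full run in minutes.

## Known limitations

Feasible GLS with estimated variance ratios carries a small O(1/C)
finite-sample drift in weakly identified terms (a few percent of the
dT² coefficient at 25 regions; verified indistinguishable between ML
and REML and absent from OLS on the same data). No temporal
autocorrelation in residuals, no non-diagonal random-effect covariance,
no errors-in-variables treatment of the climate covariates, and no
simultaneous confidence bands — pointwise intervals only.
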