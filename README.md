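# yieldclim

Quantifying how year-to-year climate variability — and in particular the
*interaction* between temperature and drought — drives variability in crop
yields. The package is aimed at agro-climatologists and biostatisticians
working with regional production panels (e.g. national statistics for
maize, rice, soybeans or wheat) together with gridded monthly temperature
and SPEI (Standardized Precipitation Evapotranspiration Index; negative =
dry, positive = wet).

## The model

For each crop, detrended log yields of all regions enter one hierarchical
linear mixed model,

```
dYield_{c,t} = (α + α_c)
             + (β + β_c)' Climate_{c,t}            # dT, dT², dS, dS²
             + (γ + γ_c)' Interactions_{c,t}       # dT·dS, dT²·dS, dT·dS², dT²·dS²
             + (δ + δ_c)' Intensification_{c,t}    # dT_{t-1}, dS_{t-1}, dT_{t-1}·dT_t, dS_{t-1}·dS_t
             + ε_{c,t}
```

where `dT`, `dS` are growing-season temperature and SPEI anomalies
(crop-calendar months, crop-area-weighted over grid cells, spline
detrended), the per-region coefficient deviations are random effects with
diagonal covariance `Σ = diag(σ₁², …, σ₁₃²)`, and residual variances are
heteroscedastic across regions, `Var(ε_{c,t}) = σ² φ_c` with `φ₁ = 1`.
Estimation is profiled maximum likelihood (the fixed effects and σ² are
concentrated out; the compiled core works on per-region sufficient
statistics). Non-significant terms are removed by backward elimination
under marginality; single-region fits use OLS with minimum-BIC selection.
Fitted log-scale effects are reported as percent yield changes,
`100·(exp(η) − 1)`, evaluated at the 0.05 / 0.50 / 0.95 quantiles of the
conditioning anomaly, with delta-method pointwise intervals. Model
variants (Full, no-interaction, linear-only) are compared by
leave-one-out cross-validation, and a noise-injection simulation tracks
how measurement error in reported yields erodes the significance of the
highest-order terms.

A synthetic-data generator with known ground truth (gridded climate, crop
calendars, area weights, production tables) makes the entire pipeline
testable without any external downloads.

## Worked example

```r
library(yieldclim)

cfg <- syn_config(n_regions = 8, n_cells_per_region = 2,
                  years = 1961:2014, seed = 42)
out <- run_pipeline(cfg, eliminate = TRUE)   # generate -> QC -> aggregate
summary(out$fit)                             # -> detrend -> fit -> curves
```

```
Hierarchical climate-yield model (ML)
  424 obs, 8 regions
              estimate         se      z         p
(Intercept) 0.00078925 0.00394754 0.1999 0.8415315
dS          0.02508505 0.00721703 3.4758 0.0005093 ***
Residual sd: 0.07865  variance ratios phi in [ 0.664, 1.573 ]
Random-effect sds:
(Intercept)          dS
   1.04e-06    1.34e-02
logLik: 454.076  BIC: -835.5553  AIC: -884.1521
```

Backward elimination kept the linear SPEI term: a one-unit SPEI anomaly
moves expected yield by about +2.5% on the log scale, with a region-level
random slope of sd 0.013 around that global mean, and residual variance
ratios between 0.66 and 1.57 across regions. The percent effect of a
joint hot-and-dry year (temperature at its 95% quantile, SPEI at its 5%
quantile) and the LOOCV comparison:

```r
qT <- climate_quantiles(out$panel, "dTemp")
qS <- climate_quantiles(out$panel, "dSPEI")
e  <- effect_at(out$fit, dT = qT[[3]], dS = qS[[1]])
# hot & dry effect: -2.8% (-4.3, -1.2)

compare_models(out$design, engine = "mixed")
#  variant  RMSE   MAE
#     Full 0.084 0.055
#  NoInter
#  OnlyLin 0.084 0.058
```

The empty NoInter row follows the reporting convention: elimination left
no interaction terms in this (small, weak-interaction) synthetic study,
so the no-interaction model coincides with the Full one. Effect curves at
the dry / median / wet SPEI quantiles are in `out$curves` and plot with
`plot(out$curves$dry)`.

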