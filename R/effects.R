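# Percent-yield-change effects: fitted log-scale effects are
# exponentiated (ratios) and one is subtracted (relative differences).
# Curves are evaluated over one climate anomaly with the conditioning
# variable pinned at empirical quantiles (0.05 dry/cold, 0.50 normal,
# 0.95 wet/hot) and everything not part of the evaluated terms at zero.

yc_anom_vars <- c(dT = "dTemp", dS = "dSPEI", lagT = "lag_dTemp",
                  lagS = "lag_dSPEI")

#' Empirical climate-anomaly quantiles
#'
#' @param panel An `"anomaly_panel"`.
#' @param var One of `"dTemp"`, `"dSPEI"`, `"lag_dTemp"`, `"lag_dSPEI"`.
#' @param probs Probabilities (default dry/cold 0.05, normal 0.50,
#'   wet/hot 0.95).
#' @param scope `"pooled"` (default) or a region label for per-region
#'   quantiles.
#' @param min_obs Minimum observations required (default 20).
#' @return Named numeric quantiles (type-7 linear interpolation, the
#'   recorded convention).
#' @export
climate_quantiles <- function(panel, var = "dSPEI",
                              probs = c(0.05, 0.5, 0.95),
                              scope = "pooled", min_obs = 20) {
  var <- match.arg(var, unname(yc_anom_vars))
  x <- if (identical(scope, "pooled")) panel[[var]] else
    panel[[var]][panel$region == scope]
  x <- x[!is.na(x)]
  if (length(x) < min_obs)
    stop("too few observations (", length(x), ") for quantiles")
  quantile(x, probs = probs, type = 7, names = TRUE)
}

# Design row for given anomaly values over the active terms, intercept
# excluded: effects are relative to the trend expectation at average
# climate.
yc_effect_row <- function(active, dT = 0, dS = 0, lagT = 0, lagS = 0) {
  ex <- yc_term_exponents()
  base <- c(dT = dT, dS = dS, lagT = lagT, lagS = lagS)
  vapply(active, function(j) {
    if (j == 1L) return(0)
    prod(base^ex[j, ])
  }, numeric(1))
}

#' Percent yield effect at given anomaly values
#'
#' Computes \eqn{\eta = c'\hat\beta} with `c` the design row for the given
#' anomalies (intercept excluded, variables not involved in any active
#' term at zero), transforms to a relative difference
#' \eqn{\exp(\eta) - 1}, and attaches the delta-method pointwise interval
#' \eqn{\exp(\eta \pm z\,\sqrt{c'\hat V c}) - 1}.
#'
#' @param fit A `"yield_mm"` or `"yield_cm"` fit.
#' @param dT,dS,lagT,lagS Anomaly values at which to evaluate.
#' @param conf Confidence level (default 0.95, normal multiplier).
#' @return List: `effect`, `lo`, `hi` (percent), `eta`, `se`.
#'   Warns when an anomaly lies outside 3x the fitted data range.
#' @export
effect_at <- function(fit, dT = 0, dS = 0, lagT = 0, lagS = 0,
                      conf = 0.95) {
  rng <- fit$design$ranges
  vals <- c(dT = unname(dT), dS = unname(dS), lagT = unname(lagT),
            lagS = unname(lagS))
  for (v in names(vals)) {
    lim <- 3 * max(abs(rng[, v]))
    if (abs(vals[v]) > lim)
      warning("anomaly ", v, " = ", vals[v],
              " lies outside 3x the data range (extrapolation)")
  }
  cc <- yc_effect_row(fit$active, vals["dT"], vals["dS"], vals["lagT"],
                      vals["lagS"])
  yc_effect_eval(fit, cc, conf)
}

# Percent effect + delta-method CI for a given contrast row.
yc_effect_eval <- function(fit, cc, conf = 0.95) {
  b <- coef(fit)
  eta <- sum(cc * b)
  se <- sqrt(max(drop(t(cc) %*% vcov(fit) %*% cc), 0))
  z <- qnorm(1 - (1 - conf) / 2)
  list(effect = 100 * (exp(eta) - 1),
       lo = 100 * (exp(eta - z * se) - 1),
       hi = 100 * (exp(eta + z * se) - 1),
       eta = eta, se = se)
}

#' Quantile-conditioned percent-yield-change curve
#'
#' Percent yield change over a grid spanning the 0.05--0.95 quantile
#' range of one climate anomaly, with an optional conditioning variable
#' pinned at an empirical quantile (e.g. the temperature curve at extreme
#' dry, median and extreme wet SPEI); for intensification curves the
#' conditioning variable is a previous-year anomaly. The curve isolates
#' the response to `x`: only terms involving `x` contribute, with the
#' conditioning value entering through its interactions with `x`. Models
#' without interaction terms therefore show one identical curve at every
#' conditioning quantile, and conditioned curves coincide at `x = 0`.
#' For the combined surface value at a joint climate state (e.g. hot and
#' dry together, including the pure conditioning-variable terms) use
#' [effect_at()].
#'
#' @param fit A `"yield_mm"` or `"yield_cm"` fit.
#' @param x Variable on the x axis: `"dT"`, `"dS"`, `"lagT"` or `"lagS"`.
#' @param panel The anomaly panel supplying empirical quantiles.
#' @param cond Optional conditioning variable (same choices as `x`).
#' @param cond_prob Quantile probability for the conditioning variable
#'   (default 0.5).
#' @param cond_value Override the conditioning value directly.
#' @param scope Quantile scope: `"pooled"` or a region label.
#' @param n Grid size (default 101).
#' @param conf Confidence level (default 0.95).
#' @return Data frame of class `"effect_curve"`: `x_var`, `x`, `effect`,
#'   `lo`, `hi`, plus metadata attributes recording every pinned value.
#' @export
effect_curve <- function(fit, x = "dT", panel, cond = NULL,
                         cond_prob = 0.5, cond_value = NULL,
                         scope = "pooled", n = 101, conf = 0.95) {
  x <- match.arg(x, names(yc_anom_vars))
  q <- climate_quantiles(panel, yc_anom_vars[[x]],
                         probs = c(0.05, 0.95), scope = scope)
  grid <- seq(q[[1]], q[[2]], length.out = n)
  pin <- c(dT = 0, dS = 0, lagT = 0, lagS = 0)
  if (!is.null(cond)) {
    cond <- match.arg(cond, names(yc_anom_vars))
    if (is.null(cond_value))
      cond_value <- unname(climate_quantiles(panel, yc_anom_vars[[cond]],
                                             probs = cond_prob,
                                             scope = scope))
    pin[cond] <- cond_value
  }
  involves_x <- yc_term_exponents()[fit$active, x] > 0
  rows <- lapply(grid, function(v) {
    a <- pin
    a[x] <- v
    cc <- yc_effect_row(fit$active, a[["dT"]], a[["dS"]], a[["lagT"]],
                        a[["lagS"]])
    cc[!involves_x] <- 0
    yc_effect_eval(fit, cc, conf)
  })
  out <- data.frame(x_var = x, x = grid,
                    effect = vapply(rows, `[[`, numeric(1), "effect"),
                    lo = vapply(rows, `[[`, numeric(1), "lo"),
                    hi = vapply(rows, `[[`, numeric(1), "hi"))
  class(out) <- c("effect_curve", "data.frame")
  attr(out, "pinned") <- pin
  attr(out, "cond") <- cond
  attr(out, "cond_prob") <- if (is.null(cond)) NA_real_ else cond_prob
  attr(out, "x_quantiles") <- q
  out
}

#' Plot a percent-yield-change curve
#'
#' Black line with a shaded pointwise confidence band and rug marks at
#' the 5 and 95% quantiles of the x variable; further curves (e.g. the
#' dry and wet conditioning quantiles) can be overlaid with `add = TRUE`
#' and a different line type.
#'
#' @param x An `"effect_curve"`.
#' @param add Overlay on an existing plot.
#' @param lty,col Line type and colour.
#' @param shade Draw the confidence band (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.effect_curve <- function(x, add = FALSE, lty = 1, col = "black",
                              shade = TRUE, ...) {
  if (!add) {
    graphics::plot(x$x, x$effect, type = "n",
                   ylim = range(x$lo, x$hi, 0, na.rm = TRUE),
                   xlab = as.character(x$x_var[1]),
                   ylab = "yield change [%]", ...)
    graphics::abline(h = 0, col = "grey70")
  }
  if (shade)
    graphics::polygon(c(x$x, rev(x$x)), c(x$lo, rev(x$hi)),
                      col = grDevices::adjustcolor(col, alpha.f = 0.15),
                      border = NA)
  graphics::lines(x$x, x$effect, lty = lty, col = col, lwd = 2)
  q <- attr(x, "x_quantiles")
  if (!is.null(q)) graphics::rug(q, col = col)
  invisible(x)
}
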