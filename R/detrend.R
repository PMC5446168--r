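# Penalized-spline detrending of log yields and growing-season climate.
# Trends are cubic regression splines of year with a shrinkage-capable
# penalty (mgcv bs = "cs"), smoothing parameter chosen by generalized
# cross-validation, so a trendless series can be penalized all the way to
# a constant. Anomalies are the residuals.

#' Maximum spline basis dimension for a yield series
#'
#' The cap is the number of years divided by ten (floored, since it is a
#' maximum), but never below 3; for series flagged as poorly fit it is
#' doubled.
#'
#' @param n_years Series length.
#' @param poor_fit Doubling flag (default `FALSE`).
#' @return Integer basis dimension.
#' @export
basis_dim_yield <- function(n_years, poor_fit = FALSE) {
  k <- max(3L, floor(n_years / 10))
  as.integer(if (poor_fit) 2L * k else k)
}

#' Fit a penalized-spline trend to a yearly series
#'
#' @param values Numeric series.
#' @param years Numeric abscissa (default `seq_along(values)`); interior
#'   gaps are permitted.
#' @param k Maximum basis dimension (must be < the number of
#'   observations).
#' @param shrink Use the shrinkage basis (`"cs"`), letting GCV penalize a
#'   trendless series to an (approximately) constant trend; otherwise
#'   `"cr"`.
#' @param gamma Inflation factor on the effective-degrees-of-freedom
#'   count in the GCV score (default 2). Plain GCV is prone to
#'   occasional severe undersmoothing; for detrending that failure mode
#'   removes exactly the year-to-year variability under study, so the
#'   smoothing choice is deliberately stringent.
#' @return An object of class `"trend_fit"`: `fitted`, `residuals`
#'   (summing back to the input exactly), `k`, `edf` (total effective
#'   degrees of freedom including the intercept), and
#'   `penalized_to_constant` (`TRUE` when the smooth is shrunk to
#'   essentially zero, edf below 1.1).
#' @export
fit_trend <- function(values, years = seq_along(values), k,
                      shrink = TRUE, gamma = 2) {
  n <- sum(!is.na(values))
  if (k >= n) stop("basis dimension k = ", k, " must be < n = ", n)
  if (sd(values, na.rm = TRUE) == 0) {
    fitted <- values
    out <- list(fitted = fitted, residuals = values - fitted, k = k,
                edf = 1, penalized_to_constant = TRUE)
    class(out) <- "trend_fit"
    return(out)
  }
  bs <- if (shrink) "cs" else "cr"
  d <- data.frame(y = values, year = years)
  g <- mgcv::gam(y ~ s(year, k = k, bs = bs), data = d,
                 method = "GCV.Cp", gamma = gamma)
  edf <- sum(g$edf)
  out <- list(fitted = as.numeric(predict(g, newdata = d)),
              residuals = d$y - as.numeric(predict(g, newdata = d)),
              k = k, edf = edf,
              penalized_to_constant = edf < 1.1)
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline trend: k = %d, edf = %.2f%s\n", x$k,
              x$edf,
              if (x$penalized_to_constant) " (shrunk to constant)" else ""))
  invisible(x)
}

# Detrend a climate panel (temp, spei) per region: k = 5, shrinkage on.
detrend_climate_panel <- function(climate, k = 5) {
  pieces <- lapply(split(climate, climate$region), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    kk <- min(k, nrow(s) - 1L)
    ft <- fit_trend(s$temp, s$year, k = kk, shrink = TRUE)
    fs <- fit_trend(s$spei, s$year, k = kk, shrink = TRUE)
    data.frame(region = s$region, year = s$year,
               dTemp = ft$residuals, dSPEI = fs$residuals)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Build the anomaly panel: detrended log yield and climate with lags
#'
#' The modelling currency of the analysis. Log is applied to yields first
#' (climate acts relatively, not absolutely), then a penalized-spline
#' trend of year is removed per region-crop series with the yield basis
#' rule ([basis_dim_yield()], doubled for series on the `poor_fit` list).
#' Growing-season temperature and SPEI are detrended with a maximum basis
#' dimension of 5 and shrinkage on. One-year lags of the climate
#' anomalies are attached; the first year of each series (and any year
#' following a gap) carries undefined lags.
#'
#' Series shorter than `min_years` are excluded with a log entry. An
#' automated residual-autocorrelation warning (lag-1 |r| > 0.5) is
#' emitted for yield trends but never auto-applied.
#'
#' @param yields Yield data frame from the QC step (`region`, `crop`,
#'   `year`, `yield`).
#' @param climate A season climate panel (`region`, `year`, `temp`,
#'   `spei`), e.g. from [aggregate_climate()].
#' @param poor_fit Character vector of `"region:crop"` keys whose yield
#'   basis dimension is doubled.
#' @param min_years Minimum usable series length (default 20).
#' @param detrend_yield Set `FALSE` to treat centred log yield as the
#'   anomaly directly (pass-through mode for data that are already
#'   trend-free).
#' @param climate_k Maximum basis dimension for climate trends (default 5).
#' @return An `"anomaly_panel"` data frame (`region`, `crop`, `year`,
#'   `dYield`, `dTemp`, `dSPEI`, `lag_dTemp`, `lag_dSPEI`) with a
#'   `diagnostics` attribute (per-series k, edf, shrink flags) recording,
#'   prominently, that log precedes detrending.
#' @export
build_anomaly_panel <- function(yields, climate, poor_fit = character(),
                                min_years = 20, detrend_yield = TRUE,
                                climate_k = 5) {
  clim_anom <- detrend_climate_panel(climate, k = climate_k)
  key <- interaction(yields$region, yields$crop, sep = ":", drop = TRUE)
  diag_rows <- list()
  excluded <- character()
  pieces <- list()
  for (kk in levels(key)) {
    s <- yields[key == kk, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    if (nrow(s) < min_years) {
      excluded <- c(excluded, kk)
      next
    }
    ly <- log(s$yield)
    if (detrend_yield) {
      kdim <- basis_dim_yield(nrow(s), poor_fit = kk %in% poor_fit)
      tf <- fit_trend(ly, s$year, k = kdim, shrink = TRUE)
      dY <- tf$residuals
      r1 <- if (length(dY) > 2)
        suppressWarnings(cor(dY[-1], dY[-length(dY)])) else 0
      if (!is.na(r1) && abs(r1) > 0.5)
        warning("residual lag-1 autocorrelation ", round(r1, 2),
                " for series ", kk,
                "; consider adding it to poor_fit")
      diag_rows[[kk]] <- data.frame(series = kk, k = kdim, edf = tf$edf,
                                    shrunk = tf$penalized_to_constant)
    } else {
      dY <- ly - mean(ly)
      diag_rows[[kk]] <- data.frame(series = kk, k = NA_integer_,
                                    edf = NA_real_, shrunk = NA)
    }
    i <- match(paste(s$region, s$year), paste(clim_anom$region,
                                              clim_anom$year))
    if (anyNA(i)) {
      # keep only years with climate coverage
      keep <- !is.na(i)
      s <- s[keep, , drop = FALSE]
      dY <- dY[keep]
      i <- i[keep]
    }
    lag_i <- match(s$year - 1L, clim_anom$year[i])
    pieces[[kk]] <- data.frame(
      region = s$region, crop = s$crop, year = s$year, dYield = dY,
      dTemp = clim_anom$dTemp[i], dSPEI = clim_anom$dSPEI[i],
      lag_dTemp = clim_anom$dTemp[i][lag_i],
      lag_dSPEI = clim_anom$dSPEI[i][lag_i])
  }
  if (!length(pieces)) stop("no usable series")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("anomaly_panel", "data.frame")
  attr(out, "diagnostics") <- do.call(rbind, diag_rows)
  attr(out, "excluded") <- excluded
  attr(out, "order_of_operations") <- "log_then_detrend"
  out
}
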