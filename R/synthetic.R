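# Synthetic-data generator: gridded monthly climate, crop calendars,
# area weights and yield panels with known ground truth, matching the
# statistical structure the analysis assumes. Defaults emulate the study
# conditions: 1961-2014 panels, standard-normal SPEI anomalies,
# growing-season temperature with seasonal cycle + trend + interannual
# anomalies, smooth saturating log-yield trends, region-varying climate
# sensitivities drawn around global means, and region-specific residual
# variance ratios.

# Default global fixed effects (log yield per unit anomaly power) and the
# random-slope standard deviations (half the absolute fixed effect; 0.02
# for the intercept). Terms follow yc_terms().
yc_default_beta <- function() {
  setNames(c(0, -0.02, -0.01, 0.03, -0.005, -0.015,
             -0.006, 0.004, -0.003, 0.006, 0.012, -0.005, 0.008),
           yc_terms())
}

yc_default_D <- function() {
  b <- yc_default_beta()
  d <- (0.5 * abs(b))^2
  d[1] <- 0.02^2
  d
}

#' Configuration for the synthetic-data generator
#'
#' Collects the study conditions the generator emulates. Defaults mirror
#' the analysis setting: 25 regions observed 1961--2014, SPEI anomalies
#' standard normal, growing-season temperature anomalies with sd 0.6 deg C,
#' a smooth saturating yield trend of amplitude 0.5 in log space, residual
#' sd 0.08 on log yield, and residual variance ratios drawn in [0.5, 2].
#'
#' @param n_regions Number of regions (>= 1).
#' @param n_cells_per_region Grid cells per region (>= 1).
#' @param years Integer vector of years (default `1961:2014`).
#' @param crop Crop label.
#' @param seasons Data frame with columns `season`, `plant_doy`,
#'   `harvest_doy`, `weight` (weights sum to 1); recycled to every region.
#'   Default: one season, planting day 121 (May 1), harvest day 274
#'   (Oct 1), weight 1.
#' @param trend_kind `"smooth"` (saturating, default), `"linear"` or
#'   `"none"` log-yield trend.
#' @param trend_amplitude Total log-yield trend rise over the period
#'   (default 0.5).
#' @param temp_trend_per_decade Linear warming trend, deg C per decade.
#' @param sd_temp_anom Sd of region-year growing-season temperature
#'   anomalies (deg C).
#' @param noise_sd_log_yield Residual sd of log yield (sigma).
#' @param phi_range Interval for residual variance ratios (lower bound
#'   > 0); the first region is pinned at 1.
#' @param spei_ar1 Year-to-year AR(1) coefficient of the shared SPEI
#'   component (default 0: independent years).
#' @param seed Integer seed; every generator operation is reproducible
#'   from it.
#' @return A validated list of class `"syn_config"`.
#' @export
syn_config <- function(n_regions = 25, n_cells_per_region = 4,
                       years = 1961:2014, crop = "maize", seasons = NULL,
                       trend_kind = c("smooth", "linear", "none"),
                       trend_amplitude = 0.5, temp_trend_per_decade = 0.25,
                       sd_temp_anom = 0.6, noise_sd_log_yield = 0.08,
                       phi_range = c(0.5, 2), spei_ar1 = 0, seed = 1L) {
  trend_kind <- match.arg(trend_kind)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_cells_per_region < 1) stop("n_cells_per_region must be >= 1")
  if (phi_range[1] <= 0) stop("phi_range lower bound must be > 0")
  if (is.null(seasons))
    seasons <- data.frame(season = 1L, plant_doy = 121L,
                          harvest_doy = 274L, weight = 1)
  if (abs(sum(seasons$weight) - 1) > 1e-8)
    stop("season weights must sum to 1")
  if (any(seasons$plant_doy < 1 | seasons$plant_doy > 365 |
          seasons$harvest_doy < 1 | seasons$harvest_doy > 365))
    stop("day-of-year values must lie in [1, 365]")
  structure(list(
    n_regions = as.integer(n_regions),
    n_cells_per_region = as.integer(n_cells_per_region),
    years = as.integer(years), crop = crop, seasons = seasons,
    trend_kind = trend_kind, trend_amplitude = trend_amplitude,
    temp_trend_per_decade = temp_trend_per_decade,
    sd_temp_anom = sd_temp_anom,
    noise_sd_log_yield = noise_sd_log_yield,
    phi_range = phi_range, spei_ar1 = spei_ar1,
    seed = as.integer(seed)), class = "syn_config")
}

#' @export
print.syn_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study configuration: %d regions x %d cells, %d-%d, crop %s\n",
    x$n_regions, x$n_cells_per_region, min(x$years), max(x$years), x$crop))
  cat(sprintf(
    "  trend %s (amplitude %.2f), sigma %.3f, phi in [%.2f, %.2f], seed %d\n",
    x$trend_kind, x$trend_amplitude, x$noise_sd_log_yield,
    x$phi_range[1], x$phi_range[2], x$seed))
  invisible(x)
}

yc_region_ids <- function(config) sprintf("R%02d", seq_len(config$n_regions))

#' Generate a gridded monthly climate panel
#'
#' Temperature per cell is a cell climatology plus a seasonal sinusoid
#' (peaking in July), a linear warming trend, a region-year shared anomaly
#' and month-level noise. SPEI is the sum of a shared region-year
#' component and independent cell-month noise with variances summing to
#' one, so the marginal distribution per cell and month is exactly
#' standard normal (the index is standardized per month and location);
#' optionally the shared component follows a stationary AR(1) across
#' years.
#'
#' @param config A [syn_config()].
#' @param month_noise_sd Sd of the month-level temperature noise.
#' @param spei_share Variance share of the shared region-year SPEI
#'   component (in `[0, 1]`).
#' @param anomaly_scale Multiplier on the temperature anomaly and noise
#'   sds (0 gives every year an identical monthly series when the warming
#'   trend is also 0).
#' @return A long data frame of class `"climate_grid"`: `cell`, `region`,
#'   `year`, `month`, `temp`, `spei`.
#' @export
gen_climate_grid <- function(config, month_noise_sd = 0.4,
                             spei_share = 0.5, anomaly_scale = 1) {
  stopifnot(inherits(config, "syn_config"))
  set.seed(config$seed + 1L)
  regions <- yc_region_ids(config)
  ncell <- config$n_cells_per_region
  cells <- sprintf("%s_c%02d", rep(regions, each = ncell),
                   rep(seq_len(ncell), config$n_regions))
  cell_region <- rep(regions, each = ncell)
  years <- config$years
  ny <- length(years)
  nc <- length(cells)

  tbar <- rnorm(nc, 15, 3)
  amp <- abs(rnorm(nc, 8, 1))
  # shared region-year anomalies
  t_anom <- matrix(rnorm(config$n_regions * ny, 0,
                         anomaly_scale * config$sd_temp_anom),
                   config$n_regions, ny)
  z <- matrix(rnorm(config$n_regions * ny), config$n_regions, ny)
  if (config$spei_ar1 != 0) {
    rho <- config$spei_ar1
    for (t in 2:ny) z[, t] <- rho * z[, t - 1] + sqrt(1 - rho^2) * z[, t]
  }

  grid <- expand.grid(month = 1:12, year = years, cell_i = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE)
  ri <- match(cell_region[grid$cell_i], regions)
  yi <- match(grid$year, years)
  seasonal <- amp[grid$cell_i] * cos(2 * pi * (grid$month - 7) / 12)
  trend <- config$temp_trend_per_decade * (grid$year - years[1]) / 10
  temp <- tbar[grid$cell_i] + seasonal + trend + t_anom[cbind(ri, yi)] +
    rnorm(nrow(grid), 0, anomaly_scale * month_noise_sd)
  spei <- sqrt(spei_share) * z[cbind(ri, yi)] +
    sqrt(1 - spei_share) * rnorm(nrow(grid))
  out <- data.frame(cell = cells[grid$cell_i],
                    region = cell_region[grid$cell_i],
                    year = grid$year, month = grid$month,
                    temp = temp, spei = spei)
  class(out) <- c("climate_grid", "data.frame")
  out
}

#' Generate per-region crop calendars
#'
#' Expands the configured seasons to every region and flags cross-year
#' seasons (harvest day-of-year before planting day-of-year).
#'
#' @param config A [syn_config()].
#' @return Data frame `region`, `crop`, `season`, `plant_doy`,
#'   `harvest_doy`, `weight`, `cross_year`.
#' @export
gen_crop_calendar <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  s <- config$seasons
  out <- do.call(rbind, lapply(yc_region_ids(config), function(r)
    data.frame(region = r, crop = config$crop, season = s$season,
               plant_doy = s$plant_doy, harvest_doy = s$harvest_doy,
               weight = s$weight,
               cross_year = s$harvest_doy < s$plant_doy)))
  rownames(out) <- NULL
  out
}

#' Generate crop-area weights per grid cell
#'
#' Random positive weights, normalized to sum to one within each region.
#'
#' @param config A [syn_config()].
#' @return Data frame `cell`, `region`, `weight`.
#' @export
gen_area_weights <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  set.seed(config$seed + 2L)
  regions <- yc_region_ids(config)
  ncell <- config$n_cells_per_region
  w <- runif(config$n_regions * ncell, 0.5, 1.5)
  out <- data.frame(
    cell = sprintf("%s_c%02d", rep(regions, each = ncell),
                   rep(seq_len(ncell), config$n_regions)),
    region = rep(regions, each = ncell), weight = w)
  out$weight <- out$weight / ave(out$weight, out$region, FUN = sum)
  out
}

#' Draw ground-truth model parameters
#'
#' Global fixed effects, diagonal random-effect variances, per-region
#' random deviations (independent normal per term), residual variance and
#' per-region variance ratios (uniform in `phi_range`, first region
#' pinned at 1). Inactive terms have zero fixed effect and zero variance.
#'
#' @param config A [syn_config()].
#' @param active Integer mask of active terms (default `1:6`: intercept,
#'   dT, dT2, dS, dS2, dT.dS). May be empty.
#' @param beta Optional 13-vector of fixed effects (default
#'   `yc_default_beta()`).
#' @param D_diag Optional 13-vector of random-effect variances (default
#'   half the absolute fixed effect, squared).
#' @param sigma2 Residual variance (default `noise_sd_log_yield^2`).
#' @return A list of class `"yc_truth"`: `beta`, `D_diag`, `sigma2`,
#'   `phi`, `b` (regions x 13), `active`.
#' @export
gen_truth <- function(config, active = 1:6, beta = NULL, D_diag = NULL,
                      sigma2 = NULL) {
  stopifnot(inherits(config, "syn_config"))
  set.seed(config$seed + 3L)
  if (is.null(beta)) beta <- yc_default_beta()
  if (is.null(D_diag)) D_diag <- yc_default_D()
  beta <- setNames(as.numeric(beta), yc_terms())
  D_diag <- setNames(as.numeric(D_diag), yc_terms())
  if (any(D_diag < 0)) stop("D_diag must be non-negative")
  mask <- rep(FALSE, 13)
  mask[active] <- TRUE
  beta[!mask] <- 0
  D_diag[!mask] <- 0
  if (is.null(sigma2)) sigma2 <- config$noise_sd_log_yield^2
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  C <- config$n_regions
  phi <- runif(C, config$phi_range[1], config$phi_range[2])
  phi[1] <- 1
  b <- matrix(rnorm(C * 13, 0, rep(sqrt(D_diag), each = C)), C, 13,
              dimnames = list(yc_region_ids(config), yc_terms()))
  structure(list(beta = beta, D_diag = D_diag, sigma2 = sigma2,
                 phi = setNames(phi, yc_region_ids(config)), b = b,
                 active = sort(unique(as.integer(active)))),
            class = "yc_truth")
}

#' @export
print.yc_truth <- function(x, ...) {
  cat("Ground-truth parameters;", length(x$phi), "regions; active terms:",
      paste(yc_terms()[x$active], collapse = ", "), "\n")
  cat("  sigma =", format(sqrt(x$sigma2)), " phi in [",
      paste(format(range(x$phi), digits = 3), collapse = ", "), "]\n")
  invisible(x)
}

# Deterministic log-yield trend on [0, 1] progress through the period.
yc_log_trend <- function(config) {
  ny <- length(config$years)
  s <- (seq_len(ny) - 1) / max(ny - 1, 1)
  switch(config$trend_kind,
         none = rep(0, ny),
         linear = config$trend_amplitude * s,
         smooth = config$trend_amplitude * (1 - exp(-3 * s)) /
           (1 - exp(-3)))
}

#' Generate a production/area panel with known truth
#'
#' Builds region-year climate anomalies (drawn directly, or derived from a
#' supplied aggregated climate panel using the same detrending the
#' analysis pipeline applies), expands them through the 13-term design,
#' and sets
#' \deqn{\log Y_{c,t} = a_c + \mathrm{trend}(t) + x_{c,t}'(\beta + b_c) +
#'   \epsilon_{c,t},\qquad \epsilon_{c,t} \sim N(0, \sigma^2 \phi_c),}
#' with a region baseline \eqn{a_c}. Emits both the observable
#' production/harvested-area table and the hidden truth (anomalies, trend,
#' noiseless decomposition) for recovery tests; the truth is returned
#' under a separate element and written with a distinct extension so
#' recovery tests never read it through the pipeline path.
#'
#' Lagged anomalies of the first year are taken as zero during generation;
#' the analysis drops first-year rows, so these never enter a fit.
#'
#' @param truth A [gen_truth()] result.
#' @param config The matching [syn_config()].
#' @param climate Optional aggregated climate panel (`region`, `year`,
#'   `temp`, `spei`); when `NULL`, anomalies are drawn directly
#'   (`dTemp ~ N(0, sd_temp_anom)`, `dSPEI ~ N(0, 1)`).
#' @param noise Multiplier on the residual sd (0 switches noise off).
#' @return A list of class `"yc_sim"` with `production` (region, crop,
#'   year, production, area), `truth_panel` (an `"anomaly_panel"` holding
#'   the true anomalies, lags and noiseless decomposition) and `truth`.
#' @export
gen_yield_panel <- function(truth, config, climate = NULL, noise = 1) {
  stopifnot(inherits(truth, "yc_truth"), inherits(config, "syn_config"))
  set.seed(config$seed + 4L)
  regions <- yc_region_ids(config)
  years <- config$years
  ny <- length(years)
  C <- length(regions)
  if (is.null(climate)) {
    dT <- matrix(rnorm(C * ny, 0, config$sd_temp_anom), C, ny)
    dS <- matrix(rnorm(C * ny), C, ny)
    if (config$spei_ar1 != 0) {
      rho <- config$spei_ar1
      for (t in 2:ny)
        dS[, t] <- rho * dS[, t - 1] + sqrt(1 - rho^2) * dS[, t]
    }
  } else {
    if (!setequal(unique(climate$region), regions))
      stop("climate panel regions do not match the configuration")
    an <- detrend_climate_panel(climate)
    dT <- matrix(NA_real_, C, ny, dimnames = list(regions, years))
    dS <- dT
    ri <- match(an$region, regions)
    yi <- match(an$year, years)
    dT[cbind(ri, yi)] <- an$dTemp
    dS[cbind(ri, yi)] <- an$dSPEI
    if (anyNA(dT) || anyNA(dS))
      stop("climate panel does not cover every region-year")
  }
  lagT <- cbind(0, dT[, -ny, drop = FALSE])
  lagS <- cbind(0, dS[, -ny, drop = FALSE])

  panel <- data.frame(
    region = rep(regions, ny), crop = config$crop,
    year = rep(years, each = C),
    dTemp = as.vector(dT), dSPEI = as.vector(dS),
    lag_dTemp = as.vector(lagT), lag_dSPEI = as.vector(lagS))
  ex <- yc_term_exponents()
  base <- cbind(panel$dTemp, panel$dSPEI, panel$lag_dTemp, panel$lag_dSPEI)
  X <- vapply(seq_len(13), function(j) {
    out <- rep(1, nrow(panel))
    for (v in 1:4) if (ex[j, v] > 0) out <- out * base[, v]^ex[j, v]
    out
  }, numeric(nrow(panel)))
  coefs <- sweep(truth$b, 2, truth$beta, `+`)  # regions x 13
  ri <- match(panel$region, regions)
  signal <- rowSums(X * coefs[ri, , drop = FALSE])

  baseline <- rnorm(C, log(3), 0.3)
  trend <- yc_log_trend(config)[match(panel$year, years)]
  eps <- rnorm(nrow(panel), 0,
               noise * sqrt(truth$sigma2 * truth$phi[ri]))
  log_yield <- baseline[ri] + trend + signal + eps
  area <- round(runif(C, 5e4, 2e5))
  production <- data.frame(
    region = panel$region, crop = panel$crop, year = panel$year,
    production = exp(log_yield) * area[ri], area = area[ri])

  truth_panel <- panel
  truth_panel$dYield <- signal + eps
  truth_panel$signal <- signal
  truth_panel$log_trend <- baseline[ri] + trend
  truth_panel$log_yield <- log_yield
  # first-year lags are a generation convention, not data: mark undefined
  truth_panel$lag_dTemp[panel$year == years[1]] <- NA
  truth_panel$lag_dSPEI[panel$year == years[1]] <- NA
  class(truth_panel) <- c("anomaly_panel", "data.frame")
  structure(list(production = production, truth_panel = truth_panel,
                 truth = truth, config = config),
            class = "yc_sim")
}

#' @export
print.yc_sim <- function(x, ...) {
  cat(sprintf("Synthetic yield panel: %d regions x %d years, crop %s\n",
              x$config$n_regions, length(x$config$years), x$config$crop))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Climate grid, production/area table, calendar and weights as CSV; the
#' hidden truth as a `.truth.json` file with a distinct extension so that
#' pipeline code never reads it by accident.
#'
#' @param config A [syn_config()].
#' @param dir Output directory (created if needed).
#' @param active,beta,D_diag,sigma2 Passed to [gen_truth()].
#' @return Invisibly, the list of written file paths.
#' @export
write_synthetic <- function(config, dir, active = 1:6, beta = NULL,
                            D_diag = NULL, sigma2 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- gen_truth(config, active = active, beta = beta,
                     D_diag = D_diag, sigma2 = sigma2)
  grid <- gen_climate_grid(config)
  cal <- gen_crop_calendar(config)
  w <- gen_area_weights(config)
  clim <- aggregate_climate(grid, cal, w, crop = config$crop)
  sim <- gen_yield_panel(truth, config, climate = clim)
  paths <- file.path(dir, c("climate_grid.csv", "production.csv",
                            "calendar.csv", "weights.csv",
                            "ground.truth.json"))
  utils::write.csv(grid, paths[1], row.names = FALSE)
  utils::write.csv(sim$production, paths[2], row.names = FALSE)
  utils::write.csv(cal, paths[3], row.names = FALSE)
  utils::write.csv(w, paths[4], row.names = FALSE)
  jsonlite::write_json(
    list(beta = truth$beta, D_diag = truth$D_diag, sigma2 = truth$sigma2,
         phi = truth$phi, b = truth$b, active = truth$active),
    paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
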