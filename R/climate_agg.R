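# Growing-season, crop-calendar and area-weighted aggregation of gridded
# monthly climate to region-year means.

# Day-of-year of the first day of each month (non-leap calendar).
yc_month_starts <- c(1, 32, 60, 91, 121, 152, 182, 213, 244, 274, 305, 335)

yc_month_of_doy <- function(doy) findInterval(doy, yc_month_starts)

#' Months of the growing season
#'
#' All months containing any day between planting and harvest, inclusive:
#' a season planted March 2 and harvested September 23 spans March through
#' September (partial months count whole). Cross-year seasons (harvest
#' day-of-year before planting day-of-year) span the year boundary and are
#' attributed to the harvest year: months of the preceding calendar year
#' carry `year_offset = -1`. The wheat rule ignores the planting date and
#' returns exactly the four months ending at the harvest month (the crop
#' is dormant and climate-insensitive over winter).
#'
#' @param plant_doy,harvest_doy Day-of-year in `[1, 365]`.
#' @param rule `"calendar"` (default) or `"wheat"`.
#' @return Data frame with `month` (1-12) and `year_offset` (0 for the
#'   harvest year, -1 for the preceding year).
#' @export
growing_season_months <- function(plant_doy, harvest_doy,
                                  rule = c("calendar", "wheat")) {
  rule <- match.arg(rule)
  if (plant_doy < 1 || plant_doy > 365 || harvest_doy < 1 ||
      harvest_doy > 365)
    stop("day-of-year values must lie in [1, 365]")
  hm <- yc_month_of_doy(harvest_doy)
  if (rule == "wheat") {
    m <- ((hm - 4 + seq_len(4)) - 1) %% 12 + 1
    off <- ifelse(m > hm, -1L, 0L)
    return(data.frame(month = m, year_offset = off))
  }
  pm <- yc_month_of_doy(plant_doy)
  if (harvest_doy >= plant_doy) {
    data.frame(month = pm:hm, year_offset = 0L)
  } else {
    m <- c(pm:12, 1:hm)
    data.frame(month = m, year_offset = ifelse(m >= pm, -1L, 0L))
  }
}

#' Unweighted mean over listed season months
#'
#' @param values Numeric vector of monthly values.
#' @param months Integer positions into `values` to average (e.g. from
#'   [growing_season_months()] resolved against a year-month layout).
#' @return Arithmetic mean; `NA` if any listed month is missing.
#' @export
season_mean <- function(values, months) {
  v <- values[months]
  if (anyNA(v)) return(NA_real_)
  mean(v)
}

#' Area-weighted regional mean
#'
#' \eqn{\sum w_i x_i / \sum w_i} over non-missing cells. If cells are
#' missing, weights are renormalized over the available ones (keeping the
#' estimator unbiased under missing-at-random cells); a warning is issued
#' when more than `warn_missing` of the weight mass is missing, and the
#' result is `NA` when everything is.
#'
#' @param x Cell values.
#' @param w Non-negative cell weights.
#' @param warn_missing Warn when the missing weight share exceeds this
#'   (default 0.25).
#' @return Scalar weighted mean.
#' @export
area_weighted_region_mean <- function(x, w, warn_missing = 0.25) {
  stopifnot(length(x) == length(w), all(w >= 0))
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  miss_share <- 1 - sum(w[ok]) / sum(w)
  if (miss_share > warn_missing)
    warning(sprintf("%.0f%% of area weight missing; renormalizing",
                    100 * miss_share))
  sum(w[ok] * x[ok]) / sum(w[ok])
}

#' Combine multi-season climate panels
#'
#' Season-weight-averages the climate values of several growing seasons
#' (e.g. two rice seasons); single-season crops pass through unchanged.
#'
#' @param panels List of data frames (`region`, `year`, `temp`, `spei`),
#'   one per season, with identical region-year keys.
#' @param weights Numeric season weights summing to 1.
#' @return One combined data frame.
#' @export
combine_multi_season <- function(panels, weights) {
  if (length(panels) != length(weights))
    stop("one weight per season panel required")
  if (abs(sum(weights) - 1) > 1e-8) stop("season weights must sum to 1")
  out <- panels[[1]]
  key <- function(p) paste(p$region, p$year)
  out$temp <- out$temp * weights[1]
  out$spei <- out$spei * weights[1]
  for (i in seq_along(panels)[-1]) {
    p <- panels[[i]]
    j <- match(key(out), key(p))
    if (anyNA(j)) stop("season panels have mismatched region-years")
    out$temp <- out$temp + weights[i] * p$temp[j]
    out$spei <- out$spei + weights[i] * p$spei[j]
  }
  out
}

# Season means per cell and harvest year for one (plant, harvest) season.
yc_cell_season_means <- function(grid_cell, months, years) {
  # grid_cell: data frame for one cell with year, month, temp, spei
  idx <- matrix(match(paste(rep(years, each = nrow(months)) +
                              rep(months$year_offset, length(years)),
                            rep(months$month, length(years))),
                      paste(grid_cell$year, grid_cell$month)),
                nrow = nrow(months))
  tmp <- matrix(grid_cell$temp[idx], nrow = nrow(months))
  spe <- matrix(grid_cell$spei[idx], nrow = nrow(months))
  data.frame(year = years, temp = colMeans(tmp), spei = colMeans(spe))
}

#' Aggregate a monthly climate grid to region-year growing-season means
#'
#' For each region and season: per-cell growing-season means per harvest
#' year (all months between planting and harvesting inclusive; the wheat
#' rule uses the four months before harvest), then crop-area weighted
#' region means, then season-weight averaging across seasons. For maize
#' only the main (highest-weight) season is used.
#'
#' @param grid A `"climate_grid"` long data frame (`cell`, `region`,
#'   `year`, `month`, `temp`, `spei`).
#' @param calendar Calendar data frame (`region`, `crop`, `season`,
#'   `plant_doy`, `harvest_doy`, `weight`).
#' @param weights Area weights (`cell`, `region`, `weight`).
#' @param crop Crop label; selects calendar rows and the crop rule
#'   (`"wheat"`: 4-month window; `"maize"`: main season only).
#' @return Data frame of class `"season_climate"`: `region`, `crop`,
#'   `year`, `temp`, `spei`. Years whose season reaches before the first
#'   data year are dropped. The year-attribution rule (harvest year) is
#'   recorded as an attribute.
#' @export
aggregate_climate <- function(grid, calendar, weights, crop) {
  cal <- calendar[calendar$crop == crop, , drop = FALSE]
  if (!nrow(cal)) stop("no calendar entries for crop ", crop)
  rule <- if (identical(crop, "wheat")) "wheat" else "calendar"
  years <- sort(unique(grid$year))
  out <- list()
  for (r in unique(cal$region)) {
    cr <- cal[cal$region == r, , drop = FALSE]
    if (identical(crop, "maize") && nrow(cr) > 1)
      cr <- cr[which.max(cr$weight), , drop = FALSE]
    w_r <- weights[weights$region == r, , drop = FALSE]
    g_r <- grid[grid$region == r, , drop = FALSE]
    season_panels <- list()
    for (s in seq_len(nrow(cr))) {
      months <- growing_season_months(cr$plant_doy[s], cr$harvest_doy[s],
                                      rule = rule)
      cell_means <- lapply(w_r$cell, function(cl)
        yc_cell_season_means(g_r[g_r$cell == cl, , drop = FALSE],
                             months, years))
      tempm <- vapply(cell_means, `[[`, numeric(length(years)), "temp")
      speim <- vapply(cell_means, `[[`, numeric(length(years)), "spei")
      season_panels[[s]] <- data.frame(
        region = r, year = years,
        temp = apply(tempm, 1, area_weighted_region_mean, w = w_r$weight),
        spei = apply(speim, 1, area_weighted_region_mean, w = w_r$weight))
    }
    wts <- cr$weight / sum(cr$weight)
    out[[r]] <- combine_multi_season(season_panels, wts)
  }
  res <- do.call(rbind, out)
  res <- data.frame(region = res$region, crop = crop, year = res$year,
                    temp = res$temp, spei = res$spei)
  res <- res[!is.na(res$temp) & !is.na(res$spei), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "year_attribution") <- "harvest_year"
  class(res) <- c("season_climate", "data.frame")
  res
}
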