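# Yield construction and data-quality filters for production/area panels.
# Reported production and area series can contain placeholder values
# (identical production reported for consecutive years) and isolated
# implausible entries; these filters turn raw tables into usable yield
# series and log every decision. QC only ever removes rows; retained
# values are never altered.

yc_add_log <- function(x, entry) {
  log <- attr(x, "qc_log")
  if (is.null(log)) log <- list()
  attr(x, "qc_log") <- c(log, list(entry))
  x
}

#' QC log of a yield series
#'
#' @param x A data frame produced by the QC functions.
#' @return A list of log entries (one per applied filter/decision).
#' @export
qc_log <- function(x) attr(x, "qc_log") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute yield from production and harvested area
#'
#' Yield is the ratio of production (tons) to harvested area (hectares).
#' Records with non-positive area, or yielding a non-positive yield, are
#' rejected and logged rather than propagated.
#'
#' @param records Data frame with columns `region`, `crop`, `year`,
#'   `production`, `area` (one record per region-crop-year).
#' @return Data frame `region`, `crop`, `year`, `production`, `area`,
#'   `yield` (t/ha), ordered by year within series, with a `qc_log`
#'   attribute listing rejected records.
#' @export
compute_yield <- function(records) {
  need <- c("region", "crop", "year", "production", "area")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(records[, c("region", "crop", "year")])
  if (any(dup)) stop("duplicate region-crop-year records")
  out <- records[order(records$region, records$crop, records$year), ]
  bad_area <- out$area <= 0
  bad_yield <- !bad_area & out$production / out$area <= 0
  log <- list()
  if (any(bad_area))
    log <- c(log, list(list(filter = "nonpositive_area",
                            dropped = out[bad_area,
                                          c("region", "crop", "year")])))
  if (any(bad_yield))
    log <- c(log, list(list(filter = "nonpositive_yield",
                            dropped = out[bad_yield,
                                          c("region", "crop", "year")])))
  out <- out[!bad_area & !bad_yield, , drop = FALSE]
  out$yield <- out$production / out$area
  rownames(out) <- NULL
  attr(out, "qc_log") <- log
  out
}

# Runs of >= 2 identical consecutive values: start/end indices.
yc_repeat_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 2L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Filter series with repeated reported production values
#'
#' If a series contains runs of two or more identical consecutive
#' production values (a hallmark of carried-forward reporting), only the
#' data strictly after the last year of the last such run, or strictly
#' before the first year of the first such run, are kept -- whichever
#' segment is longer (ties favour the more recent segment). Series that
#' fall below `min_years` after filtering are flagged unusable. The
#' filter is idempotent: a kept segment contains no further runs at its
#' relevant end, and re-application keeps it intact.
#'
#' @param series Output of [compute_yield()] (needs the `production`
#'   column).
#' @param min_years Minimum usable series length (default 20).
#' @return The filtered data frame with a `usable` attribute (named
#'   logical per region-crop series) and an extended `qc_log`.
#' @export
filter_repeated_production <- function(series, min_years = 20) {
  key <- interaction(series$region, series$crop, drop = TRUE)
  pieces <- lapply(levels(key), function(k) {
    s <- series[key == k, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    runs <- yc_repeat_runs(s$production)
    if (!nrow(runs)) return(list(data = s, log = NULL))
    after <- seq_len(nrow(s)) > max(runs$end)
    before <- seq_len(nrow(s)) < min(runs$start)
    use <- if (sum(after) >= sum(before)) after else before
    list(data = s[use, , drop = FALSE],
         log = list(filter = "repeated_production", series = k,
                    kept = if (sum(after) >= sum(before)) "after" else
                      "before",
                    dropped_years = s$year[!use]))
  })
  out <- do.call(rbind, lapply(pieces, `[[`, "data"))
  rownames(out) <- NULL
  attr(out, "qc_log") <- c(qc_log(series),
                           Filter(Negate(is.null),
                                  lapply(pieces, `[[`, "log")))
  usable <- vapply(pieces, function(p) nrow(p$data) >= min_years,
                   logical(1))
  names(usable) <- levels(key)
  attr(out, "usable") <- usable
  out
}

#' Remove configured region-crop-year observations
#'
#' Applies a manual exclusion list (isolated implausible values are
#' flagged by inspection, not by an automated rule). Entries referring to
#' absent data produce a warning, not a failure.
#'
#' @param series A yield data frame.
#' @param exclusions Data frame with columns `region`, `crop`, and either
#'   `year` or `year_from`/`year_to`; may have zero rows.
#' @return The series with the listed observations removed and logged.
#' @export
apply_exclusions <- function(series, exclusions) {
  if (is.null(exclusions) || !nrow(exclusions)) return(series)
  drop <- rep(FALSE, nrow(series))
  for (i in seq_len(nrow(exclusions))) {
    e <- exclusions[i, ]
    yrs <- if (!is.null(e$year) && !is.na(e$year)) e$year else
      seq(e$year_from, e$year_to)
    hit <- series$region == e$region & series$crop == e$crop &
      series$year %in% yrs
    if (!any(hit))
      warning("exclusion entry matches no data: ", e$region, "/", e$crop)
    drop <- drop | hit
  }
  out <- series[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "usable") <- attr(series, "usable")
  yc_add_log(structure(out, qc_log = qc_log(series)),
             list(filter = "manual_exclusions", n_dropped = sum(drop)))
}
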