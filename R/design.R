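#' @useDynLib yieldclim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif pnorm pchisq qnorm sd median
#'   nlminb cor complete.cases setNames printCoefmat coef vcov logLik
#'   fitted residuals predict simulate aggregate ave
NULL

# Exponent table of the 13 model terms over the four basic anomaly
# variables (current-year dT, dS; previous-year lagT, lagS).  Everything
# about marginality, polynomial order and design construction derives
# from this table.
yc_term_exponents <- function() {
  ex <- rbind(
    "(Intercept)" = c(0, 0, 0, 0),
    "dT"          = c(1, 0, 0, 0),
    "dT2"         = c(2, 0, 0, 0),
    "dS"          = c(0, 1, 0, 0),
    "dS2"         = c(0, 2, 0, 0),
    "dT.dS"       = c(1, 1, 0, 0),
    "dT2.dS"      = c(2, 1, 0, 0),
    "dT.dS2"      = c(1, 2, 0, 0),
    "dT2.dS2"     = c(2, 2, 0, 0),
    "lagT"        = c(0, 0, 1, 0),
    "lagS"        = c(0, 0, 0, 1),
    "lagT.dT"     = c(1, 0, 1, 0),
    "lagS.dS"     = c(0, 1, 0, 1))
  colnames(ex) <- c("dT", "dS", "lagT", "lagS")
  ex
}

#' Names of the 13 model terms
#'
#' The fixed design of the yield-variability model: intercept, linear and
#' quadratic current-year temperature and SPEI anomalies, their four
#' interaction products, the two one-year lags, and the two
#' intensification (lag-by-current) products.
#'
#' @return Character vector of length 13.
#' @export
yc_terms <- function() rownames(yc_term_exponents())

# Polynomial-order rank used by highest_order_terms(): any term involving
# >= 2 distinct variables (an interaction) outranks pure quadratics, which
# outrank linear terms; within interactions, higher total degree wins.
yc_term_rank <- function() {
  ex <- yc_term_exponents()
  nvar <- rowSums(ex > 0)
  deg <- rowSums(ex)
  ifelse(nvar >= 2, 100 + deg, deg)
}

# TRUE if term u strictly contains term v (marginality): v's exponents are
# elementwise <= u's, and u != v.
yc_contains <- function(u, v) {
  ex <- yc_term_exponents()
  all(ex[v, ] <= ex[u, ]) && any(ex[v, ] < ex[u, ])
}

# Terms in `active` that may be dropped under marginality: not the
# intercept, and not contained in any other retained term.
yc_removable <- function(active) {
  active <- sort(active)
  ok <- vapply(active, function(j) {
    if (j == 1L) return(FALSE)
    !any(vapply(setdiff(active, j), yc_contains, logical(1), v = j))
  }, logical(1))
  active[ok]
}

#' Build the 13-column model design from an anomaly panel
#'
#' Expands detrended anomalies into the polynomial/interaction design of
#' the yield-variability model. Rows whose lagged anomalies are undefined
#' (the first year of each series, or years following a gap) are dropped:
#' the lag terms are undefined there and a single model including lags is
#' fitted.
#'
#' @param panel An anomaly panel as produced by [build_anomaly_panel()] or
#'   [gen_yield_panel()]: a data frame with columns `region`, `year`,
#'   `dYield`, `dTemp`, `dSPEI`, `lag_dTemp`, `lag_dSPEI` (and optionally
#'   `crop`).
#' @return An object of class `"yield_design"`: a list with the n x 13
#'   design matrix `X`, response `y` (detrended log yield), `region`
#'   factor, `year`, the anomaly `ranges` used for extrapolation warnings,
#'   and the default `active` mask (all 13 columns).
#' @export
build_design <- function(panel) {
  need <- c("region", "year", "dYield", "dTemp", "dSPEI",
            "lag_dTemp", "lag_dSPEI")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel lacks columns: ", paste(miss, collapse = ", "))
  keep <- complete.cases(panel[, need])
  if (!any(keep)) stop("no rows with defined lagged anomalies")
  p <- panel[keep, , drop = FALSE]
  base <- cbind(dT = p$dTemp, dS = p$dSPEI,
                lagT = p$lag_dTemp, lagS = p$lag_dSPEI)
  ex <- yc_term_exponents()
  X <- vapply(seq_len(nrow(ex)), function(j) {
    out <- rep(1, nrow(p))
    for (v in 1:4) if (ex[j, v] > 0) out <- out * base[, v]^ex[j, v]
    out
  }, numeric(nrow(p)))
  colnames(X) <- rownames(ex)
  structure(list(
    X = X, y = p$dYield,
    region = factor(p$region), year = p$year,
    crop = if (!is.null(p$crop)) as.character(p$crop[1]) else NA_character_,
    ranges = apply(base, 2, range),
    active = seq_len(13L)),
    class = "yield_design")
}

#' @export
print.yield_design <- function(x, ...) {
  cat("Yield-variability model design\n")
  cat(sprintf("  %d observations, %d regions, %d terms\n",
              length(x$y), nlevels(x$region), ncol(x$X)))
  cat("  terms:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

# Subset a design to one region (used by the single-region models).
yc_design_region <- function(design, region) {
  i <- design$region == region
  if (!any(i)) stop("no rows for region ", region)
  structure(list(X = design$X[i, , drop = FALSE], y = design$y[i],
                 region = droplevels(design$region[i]), year = design$year[i],
                 crop = design$crop, ranges = design$ranges,
                 active = design$active),
            class = "yield_design")
}
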