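# Single-region models: the same 13-term design without random effects,
# fitted by ordinary least squares, with minimum-BIC term selection.

#' Fit a single-region yield model by OLS
#'
#' The same 13-term polynomial/interaction design as the hierarchical
#' model, for one region, without random effects: ordinary least squares
#' with the classical coefficient covariance
#' \eqn{\hat\sigma^2 (X'X)^{-1}}, \eqn{\hat\sigma^2 = RSS/(n - p)}.
#'
#' @param design A `"yield_design"`; if it contains several regions,
#'   `region` selects one.
#' @param active Active term columns (default all 13).
#' @param region Region label to subset to (required for multi-region
#'   designs).
#' @return An object of class `"yield_cm"` with `coefficients`, `vcov`,
#'   `sigma2`, `loglik` (Gaussian ML, used for BIC), `n`, `active`.
#' @export
fit_country <- function(design, active = NULL, region = NULL) {
  if (!is.null(region)) design <- yc_design_region(design, region)
  if (nlevels(droplevels(design$region)) > 1)
    stop("design has several regions; pass `region`")
  if (is.null(active)) active <- design$active
  active <- sort(unique(as.integer(active)))
  X <- design$X[, active, drop = FALSE]
  y <- design$y
  n <- length(y)
  p <- ncol(X)
  if (n < p + 5)
    stop(sprintf("too few observations for a %d-term fit: n = %d < %d",
                 p, n, p + 5))
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qr_x))
  V <- s2 * XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  structure(list(coefficients = setNames(beta, colnames(X)), vcov = V,
                 sigma2 = rss / n, s2_unbiased = s2, residuals = res,
                 loglik = ll, n = n, active = active,
                 region = as.character(design$region[1]),
                 crop = design$crop, design = design),
            class = "yield_cm")
}

#' @export
print.yield_cm <- function(x, ...) {
  cat("Single-region yield model (OLS), region ", x$region, "\n", sep = "")
  cat(sprintf("  n = %d, terms: %s\n", x$n,
              paste(names(x$coefficients), collapse = ", ")))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.yield_cm <- function(object, ...) {
  wt <- wald_tests(object)
  ic <- information_criteria(object)
  out <- list(region = object$region, coef_table = wt$table,
              sigma = sqrt(object$s2_unbiased), n = object$n, ic = ic)
  class(out) <- "summary.yield_cm"
  out
}

#' @export
print.summary.yield_cm <- function(x, ...) {
  cat("Single-region yield model (OLS), region ", x$region, "\n", sep = "")
  m <- as.matrix(x$coef_table[, c("estimate", "se", "z", "p")])
  rownames(m) <- x$coef_table$term
  printCoefmat(m, P.values = TRUE, has.Pvalue = TRUE)
  cat("Residual sd:", format(x$sigma, digits = 4), " n:", x$n,
      " BIC:", format(x$ic[["BIC"]]), "\n")
  invisible(x)
}

#' @export
coef.yield_cm <- function(object, ...) object$coefficients

#' @export
vcov.yield_cm <- function(object, ...) object$vcov

#' @export
logLik.yield_cm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
residuals.yield_cm <- function(object, ...) object$residuals

#' @export
fitted.yield_cm <- function(object, ...) object$design$y - object$residuals

#' @export
predict.yield_cm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  d <- if (inherits(newdata, "yield_design")) newdata else
    build_design(newdata)
  drop(d$X[, object$active, drop = FALSE] %*% object$coefficients)
}

#' Minimum-BIC term selection for a single-region model
#'
#' Greedy backward search: at each step the least significant removable
#' term (marginality respected; ties to higher polynomial order) is
#' proposed for removal, and the removal is accepted while BIC decreases;
#' the search stops at the first BIC increase. With `order = "bic"` the
#' candidate minimizing BIC among removable terms is proposed instead.
#'
#' @param design A single-region `"yield_design"` (or pass `region`).
#' @param active Starting mask (default all 13).
#' @param region Optional region to subset to.
#' @param order `"p"` (default) or `"bic"` candidate ordering.
#' @return The selected `"yield_cm"` fit with attribute `trace`, a data
#'   frame of the BIC path; the reported BIC is the minimum along it.
#' @export
bic_select <- function(design, active = NULL, region = NULL,
                       order = c("p", "bic")) {
  order <- match.arg(order)
  if (!is.null(region)) design <- yc_design_region(design, region)
  if (is.null(active)) active <- design$active
  active <- sort(unique(as.integer(active)))
  fit <- fit_country(design, active = active)
  bic <- information_criteria(fit)[["BIC"]]
  trace <- data.frame(step = 0L, dropped = NA_character_, BIC = bic)
  repeat {
    rem <- yc_removable(active)
    if (!length(rem)) break
    if (order == "p") {
      pv <- setNames(wald_tests(fit)$table$p, names(coef(fit)))
      cand <- yc_drop_candidate(active, pv)
      cols <- cand$col
    } else {
      cols <- rem[order(vapply(rem, function(j)
        information_criteria(
          fit_country(design, active = setdiff(active, j)))[["BIC"]],
        numeric(1)))][1]
    }
    fit2 <- fit_country(design, active = setdiff(active, cols))
    bic2 <- information_criteria(fit2)[["BIC"]]
    if (bic2 >= bic) break
    active <- setdiff(active, cols)
    fit <- fit2
    bic <- bic2
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     dropped = yc_terms()[cols], BIC = bic))
  }
  attr(fit, "trace") <- trace
  fit
}
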