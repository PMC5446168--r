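# Wald inference, information criteria and marginality-respecting
# backward elimination, shared by the mixed (panel) and single-region
# (OLS) fits.

#' Wald tests of model terms
#'
#' Per-coefficient tests (estimate / standard error) and, optionally,
#' joint tests of term groups via the quadratic form
#' \eqn{\hat\beta_g' V_g^{-1} \hat\beta_g}. The mixed model uses the
#' large-sample normal/chi-square reference; single-region OLS fits use
#' the exact classical t/F reference with their residual degrees of
#' freedom.
#'
#' @param fit A `"yield_mm"` or `"yield_cm"` fit.
#' @param groups Optional named list of character vectors of term names
#'   (or integer column indices into the 13-term design) to test jointly.
#' @return A list with `table` (term, estimate, se, z, p) and, if groups
#'   were given, `joint` (group, chisq, df, p). Zero standard errors give
#'   `NA` p-values with a flag.
#' @export
wald_tests <- function(fit, groups = NULL) {
  b <- coef(fit)
  V <- vcov(fit)
  df_res <- if (inherits(fit, "yield_cm"))
    fit$n - length(b) else Inf
  se <- sqrt(pmax(diag(V), 0))
  z <- ifelse(se > 0, b / se, NA_real_)
  p <- if (is.finite(df_res)) 2 * stats::pt(-abs(z), df_res) else
    2 * pnorm(-abs(z))
  p[is.na(z)] <- NA_real_
  tab <- data.frame(term = names(b), estimate = unname(b), se = se, z = z,
                    p = p, zero_se = se == 0, row.names = NULL)
  out <- list(table = tab)
  if (!is.null(groups)) {
    all_terms <- yc_terms()
    jt <- lapply(names(groups), function(g) {
      gg <- groups[[g]]
      if (is.numeric(gg)) gg <- all_terms[gg]
      i <- match(gg, names(b))
      if (anyNA(i)) stop("group ", g, " refers to inactive terms")
      W <- tryCatch(
        drop(t(b[i]) %*% solve(V[i, i, drop = FALSE], b[i])),
        error = function(e) NA_real_)
      k <- length(i)
      pj <- if (is.finite(df_res))
        stats::pf(W / k, k, df_res, lower.tail = FALSE) else
          pchisq(W, k, lower.tail = FALSE)
      data.frame(group = g, chisq = W, df = k, p = pj)
    })
    out$joint <- do.call(rbind, jt)
  }
  out
}

#' Information criteria of a fit
#'
#' BIC and AIC from the maximized (ML) log-likelihood, counting active
#' fixed effects plus active variance parameters (residual variance,
#' random-effect variances if present, variance ratios if present).
#' `n` is the number of rows that entered the fit.
#'
#' @param fit A `"yield_mm"` or `"yield_cm"` fit (ML).
#' @return Named vector `c(BIC, AIC, df, n)`.
#' @export
information_criteria <- function(fit) {
  ll <- as.numeric(logLik(fit))
  p <- attr(logLik(fit), "df")
  n <- attr(logLik(fit), "nobs")
  c(BIC = -2 * ll + p * log(n), AIC = -2 * ll + 2 * p, df = p, n = n)
}

# One elimination step: among removable terms (marginality), the one with
# the largest p-value; ties broken by higher polynomial order first, then
# higher column index.
yc_drop_candidate <- function(active, pvals) {
  rem <- yc_removable(active)
  if (!length(rem)) return(NULL)
  nm <- yc_terms()[rem]
  p <- pvals[nm]
  rank <- yc_term_rank()[rem]
  ord <- order(-p, -rank, -rem)
  list(col = rem[ord[1]], p = unname(p[ord[1]]))
}

#' Backward elimination of non-significant terms
#'
#' Starting from the full active mask, iteratively removes the least
#' significant removable term with p-value above `alpha`, respecting
#' marginality (a lower-order term is never removed while a retained
#' higher-order term contains it). For the mixed model the fixed and
#' random parts of a term are removed together, so the random structure
#' shrinks in step with the fixed structure.
#'
#' @param design A `"yield_design"`.
#' @param active Starting mask (default all 13 columns).
#' @param alpha Significance level for removal (default 0.05).
#' @param engine `"mixed"` (default) or `"country"` (single-region OLS).
#' @param ... Passed to [fit_mixed()] or [fit_country()].
#' @return The final fit, with an attached `trace` data frame recording
#'   every step (dropped term, its p-value, log-likelihood and BIC of the
#'   model it was dropped from).
#' @export
backward_eliminate <- function(design, active = NULL, alpha = 0.05,
                               engine = c("mixed", "country"), ...) {
  engine <- match.arg(engine)
  if (is.null(active)) active <- design$active
  active <- sort(unique(as.integer(active)))
  fitter <- if (engine == "mixed") fit_mixed else fit_country
  trace <- list()
  repeat {
    fit <- fitter(design, active = active, ...)
    wt <- wald_tests(fit)
    pv <- setNames(wt$table$p, wt$table$term)
    cand <- yc_drop_candidate(active, pv)
    ic <- information_criteria(fit)
    if (is.null(cand) || is.na(cand$p) || cand$p <= alpha) break
    trace[[length(trace) + 1]] <- data.frame(
      step = length(trace) + 1L, dropped = yc_terms()[cand$col],
      p = cand$p, loglik = as.numeric(logLik(fit)), BIC = ic[["BIC"]])
    active <- setdiff(active, cand$col)
  }
  attr(fit, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), dropped = character(), p = numeric(),
               loglik = numeric(), BIC = numeric())
  fit
}
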