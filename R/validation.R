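# Leave-one-out cross-validation and nested-model comparison
# (Full / NoInter / OnlyLin).

#' Leave-one-out cross-validation of a yield model
#'
#' The active mask is fixed before cross-validation; no re-selection
#' happens inside folds. For the mixed model, each fold re-estimates the
#' fixed effects (GLS) and the held-out region's BLUP from the remaining
#' data, with the variance parameters frozen at their full-data ML values
#' by default (`refit_variance = TRUE` refits them in every fold, at
#' roughly n times the cost); the held-out observation is predicted with
#' fixed effects plus its region's BLUP. For the single-region OLS model
#' the exact closed-form deletion residuals are used. The procedure is
#' deterministic and invariant to observation order.
#'
#' @param design A `"yield_design"`.
#' @param active Active mask (fixed in advance).
#' @param engine `"mixed"` or `"country"`.
#' @param region For `engine = "country"` with a multi-region design.
#' @param refit_variance Refit variance parameters per fold (mixed only).
#' @param min_region_rows Folds that would drop a region below this many
#'   rows are skipped and logged (default 3).
#' @param fit Optionally, a pre-computed full-data fit with this mask.
#' @return List of class `"cv_result"`: `rmse` (root mean square
#'   prediction error on the log scale), `mae` (median absolute error),
#'   `n` held-out predictions, `errors`, `skipped`.
#' @export
loocv <- function(design, active = NULL, engine = c("mixed", "country"),
                  region = NULL, refit_variance = FALSE,
                  min_region_rows = 3, fit = NULL) {
  engine <- match.arg(engine)
  if (engine == "country") {
    if (!is.null(region)) design <- yc_design_region(design, region)
    f <- if (is.null(fit)) fit_country(design, active = active) else fit
    X <- design$X[, f$active, drop = FALSE]
    qr_x <- qr(X)
    h <- rowSums(qr.Q(qr_x)^2)
    e <- residuals(f) / (1 - h)
    return(structure(list(rmse = sqrt(mean(e^2)), mae = median(abs(e)),
                          n = length(e), errors = e, skipped = 0L),
                     class = "cv_result"))
  }
  f <- if (is.null(fit)) fit_mixed(design, active = active) else fit
  active <- f$active
  st <- f$stats
  q <- st$q
  lambda <- f$lambda
  phi <- f$phi
  X <- design$X[, active, drop = FALSE]
  y <- design$y
  region_f <- droplevels(design$region)
  ci <- match(as.character(region_f), st$regions)
  errors <- rep(NA_real_, length(y))
  skipped <- 0L
  for (i in seq_along(y)) {
    c <- ci[i]
    if (st$nv[c] - 1 < min_region_rows) {
      skipped <- skipped + 1L
      next
    }
    A <- st$A
    U <- st$U
    s <- st$s
    nv <- st$nv
    x <- X[i, ]
    A[, , c] <- A[, , c] - tcrossprod(x)
    U[, c] <- U[, c] - x * y[i]
    s[c] <- s[c] - y[i]^2
    nv[c] <- nv[c] - 1
    if (refit_variance) {
      obj <- function(theta)
        mm_nll_cpp(theta, A, U, s, nv, f$random, f$het, f$method == "REML")
      opt <- nlminb(f$theta, obj, lower = -30, upper = 30,
                    control = list(rel.tol = 1e-10))
      k <- 0L
      lam_i <- rep(0, q)
      if (f$random) { lam_i <- exp(opt$par[seq_len(q)]); k <- q }
      phi_i <- rep(1, st$C)
      if (f$het) phi_i[-1] <- exp(opt$par[k + seq_len(st$C - 1)])
    } else {
      lam_i <- lambda
      phi_i <- phi
    }
    ev <- mm_eval_cpp(A, U, s, nv, lam_i, phi_i,
                      f$method == "REML", TRUE)
    pred <- sum(x * (drop(ev$beta) + ev$blup[, c]))
    errors[i] <- y[i] - pred
  }
  errors <- errors[!is.na(errors)]
  structure(list(rmse = sqrt(mean(errors^2)), mae = median(abs(errors)),
                 n = length(errors), errors = errors, skipped = skipped),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV: RMSE %.4f, MAE %.4f over %d held-out predictions",
              x$rmse, x$mae, x$n))
  if (x$skipped > 0) cat(sprintf(" (%d folds skipped)", x$skipped))
  cat("\n")
  invisible(x)
}

# Interaction columns of the 13-term design.
yc_interaction_cols <- function() {
  which(rowSums(yc_term_exponents() > 0) >= 2)
}

# Linear-only columns: intercept, dT, dS, lagT, lagS.
yc_linear_cols <- function() {
  ex <- yc_term_exponents()
  which(rowSums(ex) <= 1)
}

#' Compare Full, NoInter and OnlyLin model variants by LOOCV
#'
#' Reproduces the nested-variant comparison: the Full model is selected
#' by backward elimination from the complete 13-term design; NoInter
#' starts from the design without interaction terms (variables may still
#' be linear or quadratic) and is re-eliminated; OnlyLin contains only
#' the linear terms (intercept, dT, dS and the two lags). OnlyLin is
#' nested within NoInter, which is nested within Full. When a simpler
#' variant selects the same terms as the more complex one its cells are
#' left empty (`NA`), mirroring the reporting convention.
#'
#' @param design A `"yield_design"`.
#' @param engine `"mixed"` or `"country"`.
#' @param region Region for the country engine.
#' @param alpha Elimination level (default 0.05).
#' @param refit_variance Passed to [loocv()].
#' @param eliminate Run backward elimination for Full/NoInter (default
#'   `TRUE`); with `FALSE` the full masks are used as-is.
#' @param ... Passed to the fitters.
#' @return Data frame of class `"cv_table"`: variant, rmse, mae, n,
#'   terms (comma-separated), shown (`FALSE` for empty cells).
#' @export
compare_models <- function(design, engine = c("mixed", "country"),
                           region = NULL, alpha = 0.05,
                           refit_variance = FALSE, eliminate = TRUE, ...) {
  engine <- match.arg(engine)
  if (engine == "country" && !is.null(region))
    design <- yc_design_region(design, region)
  select <- function(start) {
    if (!eliminate) return(start)
    if (engine == "mixed")
      backward_eliminate(design, active = start, alpha = alpha,
                         engine = "mixed", ...)$active
    else
      bic_select(design, active = start)$active
  }
  masks <- list(
    Full = select(1:13),
    NoInter = select(setdiff(1:13, yc_interaction_cols())),
    OnlyLin = yc_linear_cols())
  shown <- c(Full = TRUE,
             NoInter = !setequal(masks$NoInter, masks$Full),
             OnlyLin = !setequal(masks$OnlyLin, masks$NoInter))
  rows <- lapply(names(masks), function(v) {
    cv <- loocv(design, active = masks[[v]], engine = engine,
                refit_variance = refit_variance)
    data.frame(variant = v,
               rmse = if (shown[[v]]) cv$rmse else NA_real_,
               mae = if (shown[[v]]) cv$mae else NA_real_,
               n = cv$n,
               terms = paste(yc_terms()[masks[[v]]], collapse = ","),
               shown = shown[[v]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_table", "data.frame")
  attr(out, "masks") <- masks
  out
}

#' @export
print.cv_table <- function(x, digits = 3, ...) {
  d <- data.frame(variant = x$variant,
                  RMSE = ifelse(x$shown, format(round(x$rmse, digits)), ""),
                  MAE = ifelse(x$shown, format(round(x$mae, digits)), ""))
  print(d, row.names = FALSE)
  invisible(x)
}
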