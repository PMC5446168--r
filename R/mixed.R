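# Hierarchical yield-variability model: 13 fixed effects with matching
# per-region random slopes (diagonal covariance Sigma = diag(sigma_1^2,
# ..., sigma_13^2)) and region-specific residual variance ratios phi_c
# (phi_1 = 1). Estimation is maximum likelihood with beta and sigma^2
# profiled out; the free parameters are log relative random-effect
# variances and log variance ratios.

# Per-region sufficient statistics for the active columns.
yc_region_stats <- function(X, y, region) {
  lev <- levels(region)
  q <- ncol(X)
  C <- length(lev)
  A <- array(0, c(q, q, C))
  U <- matrix(0, q, C)
  s <- numeric(C)
  nv <- numeric(C)
  for (c in seq_along(lev)) {
    i <- which(region == lev[c])
    Xc <- X[i, , drop = FALSE]
    A[, , c] <- crossprod(Xc)
    U[, c] <- crossprod(Xc, y[i])
    s[c] <- sum(y[i]^2)
    nv[c] <- length(i)
  }
  list(A = A, U = U, s = s, nv = nv, regions = lev, q = q, C = C,
       n = sum(nv))
}

#' Fit the hierarchical climate-yield variability model
#'
#' Fits, by maximum likelihood, a linear mixed model for detrended log
#' yields with global fixed effects for the active design terms, matching
#' per-region random deviations with diagonal covariance, and
#' region-specific residual variance ratios:
#' \deqn{y_{c,t} = x_{c,t}'(\beta + b_c) + \epsilon_{c,t},\quad
#'   b_c \sim N(0, \mathrm{diag}(\sigma_1^2,\dots,\sigma_q^2)),\quad
#'   \mathrm{Var}(\epsilon_{c,t}) = \sigma^2 \phi_c,\ \phi_1 = 1.}
#' The fixed effects are profiled out by generalized least squares at each
#' variance evaluation and variance parameters are optimized on the log
#' scale, so the fit is deterministic given data and starting point.
#'
#' @param design A `"yield_design"` object from [build_design()].
#' @param active Integer vector of active term columns (default: the
#'   design's mask, all 13). The same mask drives both the fixed and the
#'   random part: eliminating a term removes both.
#' @param random Include per-region random slopes (default `TRUE`).
#' @param het Estimate per-region residual variance ratios (default
#'   `TRUE`). With `random = FALSE, het = FALSE` the fit reduces exactly
#'   to ordinary least squares.
#' @param method `"ML"` (default; valid for BIC comparisons across fixed
#'   structures) or `"REML"`.
#' @param start Optional numeric starting vector for the log variance
#'   parameters.
#' @param n_starts Number of deterministic starting points (default 1;
#'   use 3 for flat likelihoods).
#' @param control Passed to [stats::nlminb()] (defaults: `rel.tol 1e-12`,
#'   generous evaluation limits).
#' @return An object of class `"yield_mm"`; see [summary.yield_mm()].
#'   Components include `coefficients`, `vcov`, `sigma2`, `D_diag`
#'   (absolute random-effect variances), `phi`, `blup` (regions x terms),
#'   `loglik`, `active`, and a `convergence` report.
#' @seealso [backward_eliminate()], [wald_tests()], [information_criteria()]
#' @export
fit_mixed <- function(design, active = NULL, random = TRUE, het = TRUE,
                      method = c("ML", "REML"), start = NULL, n_starts = 1,
                      control = list()) {
  method <- match.arg(method)
  reml <- method == "REML"
  if (is.null(active)) active <- design$active
  active <- sort(unique(as.integer(active)))
  X <- design$X[, active, drop = FALSE]
  y <- design$y
  region <- droplevels(design$region)
  C <- nlevels(region)
  if (C < 2) stop("mixed model requires >= 2 regions; see fit_country()")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  st <- yc_region_stats(X, y, region)
  q <- st$q
  n_theta <- (if (random) q else 0L) + (if (het) C - 1L else 0L)
  ctrl <- utils::modifyList(
    list(rel.tol = 1e-12, eval.max = 5000, iter.max = 2000), control)

  if (n_theta == 0L) {
    opt <- list(par = numeric(0), convergence = 0L, objective = NA_real_)
  } else {
    obj <- function(theta)
      mm_nll_cpp(theta, st$A, st$U, st$s, st$nv, random, het, reml)
    starts <- list(if (is.null(start)) rep(c(-3, 0),
                                           c(if (random) q else 0,
                                             if (het) C - 1 else 0))
                   else start)
    if (n_starts > 1) {
      offs <- c(-2, 2, -4)
      for (k in seq_len(n_starts - 1))
        starts[[k + 1]] <- starts[[1]] + offs[(k - 1) %% 3 + 1]
    }
    fits <- lapply(starts, function(s0)
      nlminb(s0, obj, lower = -30, upper = 30, control = ctrl))
    opt <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  }

  k <- 0L
  lambda <- rep(0, q)
  if (random) { lambda <- exp(opt$par[seq_len(q)]); k <- q }
  phi <- rep(1, C)
  if (het && C > 1) phi[-1] <- exp(opt$par[k + seq_len(C - 1)])
  ev <- mm_eval_cpp(st$A, st$U, st$s, st$nv, lambda, phi, reml, TRUE)

  grad_norm <- NA_real_
  if (n_theta > 0L) {
    h <- 1e-5
    g <- vapply(seq_len(n_theta), function(j) {
      e <- numeric(n_theta); e[j] <- h
      (obj(opt$par + e) - obj(opt$par - e)) / (2 * h)
    }, numeric(1))
    grad_norm <- sqrt(sum(g^2))
  }
  boundary <- n_theta > 0L && any(abs(opt$par) > 29.5)

  beta <- setNames(drop(ev$beta), colnames(X))
  Vb <- ev$sigma2 * solve(ev$H)
  dimnames(Vb) <- list(colnames(X), colnames(X))
  blup <- t(ev$blup)  # regions x q (computed with absolute D via lambda*sigma2 profiling)
  dimnames(blup) <- list(st$regions, colnames(X))

  structure(list(
    coefficients = beta, vcov = Vb,
    sigma2 = ev$sigma2,
    D_diag = setNames(lambda * ev$sigma2, colnames(X)),
    lambda = setNames(lambda, colnames(X)),
    phi = setNames(phi, st$regions),
    blup = blup,
    loglik = ev$loglik,
    n_obs = st$n, n_regions = C,
    active = active, random = random, het = het, method = method,
    convergence = list(code = opt$convergence,
                       # variances clamped at the boundary routinely
                       # trigger nlminb's "false convergence" code; a
                       # small gradient norm is the operative check
                       converged = identical(opt$convergence, 0L) ||
                         (is.finite(grad_norm) && grad_norm < 1e-3),
                       grad_norm = grad_norm, boundary = boundary),
    theta = opt$par, stats = st, design = design),
    class = "yield_mm")
}

#' Exact marginal log-likelihood of the mixed model
#'
#' Gaussian log density of the observed responses with the random effects
#' integrated out, summed over region blocks: each block has covariance
#' \eqn{V_c = Z_c D Z_c' + \sigma^2 \phi_c I} with \eqn{Z_c} equal to the
#' active design columns and \eqn{D} diagonal.
#'
#' @param design A `"yield_design"`.
#' @param beta Fixed-effect vector (length = number of active columns).
#' @param D_diag Non-negative random-effect variances (same length).
#' @param sigma2 Residual variance (> 0).
#' @param phi Per-region variance ratios, in the order of
#'   `levels(design$region)`; the first is conventionally 1.
#' @param active Active columns (default all 13).
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(design, beta, D_diag, sigma2, phi,
                            active = NULL) {
  if (is.null(active)) active <- design$active
  X <- design$X[, active, drop = FALSE]
  y <- design$y
  region <- droplevels(design$region)
  q <- ncol(X)
  stopifnot(length(beta) == q, length(D_diag) == q, sigma2 > 0,
            all(D_diag >= 0), length(phi) == nlevels(region), all(phi > 0))
  sl <- sqrt(D_diag)
  ll <- 0
  for (r in levels(region)) {
    i <- which(region == r)
    ph <- phi[match(r, levels(region))]
    Xc <- X[i, , drop = FALSE]
    rc <- y[i] - drop(Xc %*% beta)
    A <- crossprod(Xc)
    u <- drop(crossprod(Xc, rc))
    v <- sigma2 * ph
    M <- A * tcrossprod(sl) / v
    diag(M) <- diag(M) + 1
    R <- tryCatch(chol(M), error = function(e)
      stop("non-PSD covariance block for region ", r,
           "; min eigenvalue ", format(min(eigen(M)$values))))
    ldet <- length(i) * log(v) + 2 * sum(log(diag(R)))
    su <- sl * u / v
    w <- backsolve(R, backsolve(R, su, transpose = TRUE))
    quad <- (sum(rc^2) - sum((sl * u) * w)) / v
    ll <- ll - 0.5 * (length(i) * log(2 * pi) + ldet + quad)
  }
  ll
}

#' @export
print.yield_mm <- function(x, ...) {
  cat("Hierarchical climate-yield model (", x$method, ")\n", sep = "")
  cat(sprintf("  %d obs, %d regions; active terms: %s\n", x$n_obs,
              x$n_regions, paste(names(x$coefficients), collapse = ", ")))
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("Fixed effects:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.yield_mm <- function(object, ...) {
  wt <- wald_tests(object)
  out <- list(call_terms = names(object$coefficients),
              coef_table = wt$table,
              sigma = sqrt(object$sigma2),
              D_diag = object$D_diag,
              phi_range = range(object$phi),
              loglik = object$loglik,
              ic = information_criteria(object),
              n_obs = object$n_obs, n_regions = object$n_regions,
              method = object$method,
              convergence = object$convergence)
  class(out) <- "summary.yield_mm"
  out
}

#' @export
print.summary.yield_mm <- function(x, ...) {
  cat("Hierarchical climate-yield model (", x$method, ")\n", sep = "")
  cat(sprintf("  %d obs, %d regions\n", x$n_obs, x$n_regions))
  m <- as.matrix(x$coef_table[, c("estimate", "se", "z", "p")])
  rownames(m) <- x$coef_table$term
  printCoefmat(m, P.values = TRUE, has.Pvalue = TRUE)
  cat("Residual sd:", format(x$sigma, digits = 4),
      " variance ratios phi in [",
      paste(format(x$phi_range, digits = 3), collapse = ", "), "]\n")
  cat("Random-effect sds:\n")
  print(signif(sqrt(x$D_diag), 3))
  cat("logLik:", format(x$loglik), " BIC:", format(x$ic[["BIC"]]),
      " AIC:", format(x$ic[["AIC"]]), "\n")
  if (!isTRUE(x$convergence$converged))
    cat("WARNING: optimizer did not report clean convergence\n")
  invisible(x)
}

#' @export
coef.yield_mm <- function(object, ...) object$coefficients

#' @export
vcov.yield_mm <- function(object, ...) object$vcov

#' @export
logLik.yield_mm <- function(object, ...) {
  p <- length(object$coefficients) +
    (if (object$random) length(object$coefficients) else 0L) + 1L +
    (if (object$het) object$n_regions - 1L else 0L)
  structure(object$loglik, df = p, nobs = object$n_obs, class = "logLik")
}

#' Region-level random-effect predictions (BLUPs)
#'
#' Empirical best linear unbiased predictors of the per-region coefficient
#' deviations, \eqn{b_c = D Z_c' V_c^{-1} (y_c - X_c \hat\beta)}.
#'
#' @param object A fitted `"yield_mm"`.
#' @param ... Unused.
#' @return A regions x active-terms matrix; rows of inactive or
#'   non-random fits are zero.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.yield_mm <- function(object, ...) object$blup

#' @export
fitted.yield_mm <- function(object, level = 1, ...) {
  d <- object$design
  X <- d$X[, object$active, drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (level >= 1 && object$random) {
    b <- object$blup[as.character(d$region), , drop = FALSE]
    eta <- eta + rowSums(X * b)
  }
  eta
}

#' @export
residuals.yield_mm <- function(object, level = 1, ...) {
  object$design$y - fitted(object, level = level)
}

#' @export
predict.yield_mm <- function(object, newdata = NULL, level = 1, ...) {
  if (is.null(newdata)) return(fitted(object, level = level))
  d <- if (inherits(newdata, "yield_design")) newdata else
    build_design(newdata)
  X <- d$X[, object$active, drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (level >= 1 && object$random) {
    reg <- as.character(d$region)
    known <- reg %in% rownames(object$blup)
    b <- matrix(0, nrow(X), ncol(X))
    b[known, ] <- object$blup[reg[known], , drop = FALSE]
    eta <- eta + rowSums(X * b)
  }
  eta
}

#' Simulate responses from a fitted mixed model
#'
#' Draws new per-region random deviations and heteroscedastic residuals at
#' the fitted parameters; useful for parametric-bootstrap style checks.
#'
#' @param object A fitted `"yield_mm"`.
#' @param nsim Number of response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix with one column per simulation.
#' @export
simulate.yield_mm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$design
  X <- d$X[, object$active, drop = FALSE]
  reg <- droplevels(d$region)
  C <- nlevels(reg)
  q <- ncol(X)
  out <- matrix(NA_real_, nrow(X), nsim)
  mu <- drop(X %*% object$coefficients)
  for (s in seq_len(nsim)) {
    b <- matrix(rnorm(C * q, 0, rep(sqrt(object$D_diag), each = C)), C, q)
    eps <- rnorm(nrow(X), 0,
                 sqrt(object$sigma2 * object$phi[as.integer(reg)]))
    out[, s] <- mu + rowSums(X * b[as.integer(reg), , drop = FALSE]) + eps
  }
  out
}
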