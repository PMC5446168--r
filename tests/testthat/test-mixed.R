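# The hierarchical mixed model: likelihood oracle, degenerate limits,
# recovery, equivariance, BLUP identities, information criteria and the
# independent nlme cross-check.

test_that("marginal likelihood equals the brute-force joint density", {
  for (conf in list(list(C = 2, yrs = 2004:2010, act = c(1, 2, 4)),
                    list(C = 3, yrs = 2003:2010, act = 1:6),
                    list(C = 5, yrs = 2001:2010, act = c(1, 2, 3, 4)))) {
    s <- sim_design(seed = conf$C, C = conf$C, years = conf$yrs,
                    active = conf$act)
    q <- length(conf$act)
    beta <- seq(-0.02, 0.02, length.out = q)
    D <- seq(1e-4, 5e-4, length.out = q)
    phi <- seq(1, 1.8, length.out = conf$C)
    ll <- marginal_loglik(s$design, beta, D, 0.0064, phi,
                          active = conf$act)
    llb <- brute_loglik(s$design, beta, D, 0.0064, phi, conf$act)
    expect_lt(abs(ll - llb), 1e-8)
  }
})

test_that("with D = 0 and phi = 1 the likelihood is the iid normal one", {
  s <- sim_design(seed = 7, C = 3, years = 2000:2012, active = c(1, 2, 4))
  act <- c(1, 2, 4)
  beta <- c(0.01, -0.02, 0.03)
  s2 <- 0.005
  ll <- marginal_loglik(s$design, beta, rep(0, 3), s2, rep(1, 3),
                        active = act)
  r <- s$design$y - drop(s$design$X[, act] %*% beta)
  ll_iid <- sum(dnorm(r, 0, sqrt(s2), log = TRUE))
  expect_equal(ll, ll_iid, tolerance = 1e-10)
})

test_that("likelihood is invariant to region order", {
  s <- sim_design(seed = 8, C = 4, years = 2000:2012, active = 1:6)
  d <- s$design
  set.seed(1)
  p <- sample(length(d$y))
  d2 <- d
  d2$X <- d$X[p, ]
  d2$y <- d$y[p]
  d2$region <- d$region[p]
  d2$year <- d$year[p]
  a <- c(1, 2, 4, 6)
  args <- list(beta = c(0, -0.02, 0.03, -0.01), D = rep(2e-4, 4),
               s2 = 0.006, phi = c(1, 0.6, 1.4, 1.9))
  expect_equal(
    marginal_loglik(d, args$beta, args$D, args$s2, args$phi, active = a),
    marginal_loglik(d2, args$beta, args$D, args$s2, args$phi, active = a))
})

test_that("degenerate truth (D=0, phi=1) is recovered and matches OLS", {
  skipped <- 0
  for (r in 1:20) {
    s <- sim_design(seed = 100 + r, C = 5, years = 1985:2014,
                    active = c(1, 2, 4), D = rep(0, 13),
                    phi_range = c(1, 1))
    f0 <- fit_mixed(s$design, active = c(1, 2, 4), random = FALSE,
                    het = FALSE)
    ols <- qr.coef(qr(s$design$X[, c(1, 2, 4)]), s$design$y)
    expect_lt(max(abs(coef(f0) - ols)), 1e-8)
    # full machinery drives D_diag towards zero
    f <- fit_mixed(s$design, active = c(1, 2, 4))
    expect_lt(max(f$D_diag), 1e-3)
    # fixed effects near truth on the analytic OLS standard-error scale
    # (4 sigma: 60 draws make an occasional 3.5-sigma excursion routine)
    se <- sqrt(diag(solve(crossprod(s$design$X[, c(1, 2, 4)]))) *
                 s$truth$sigma2)
    expect_true(all(abs(coef(f) - s$truth$beta[c(1, 2, 4)]) < 4 * se))
  }
})

test_that("maximum-likelihood beats the generating parameters' likelihood", {
  wins <- vapply(1:25, function(r) {
    s <- sim_design(seed = 300 + r, C = 5, years = 1995:2014,
                    active = c(1, 2, 4))
    f <- fit_mixed(s$design, active = c(1, 2, 4))
    D_t <- pmax(s$truth$D_diag[c(1, 2, 4)], 1e-12)
    ll_t <- marginal_loglik(s$design, s$truth$beta[c(1, 2, 4)], D_t,
                            s$truth$sigma2, s$truth$phi,
                            active = c(1, 2, 4))
    f$loglik >= ll_t - 1e-6
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("rescaling dT rescales coefficients equivariantly", {
  s <- sim_design(seed = 12, C = 6, years = 1985:2014, active = 1:6)
  f1 <- fit_mixed(s$design, active = 1:6)
  k <- 2.5
  p2 <- s$panel
  p2$dTemp <- k * p2$dTemp
  p2$lag_dTemp <- k * p2$lag_dTemp
  f2 <- fit_mixed(build_design(p2), active = 1:6)
  expect_equal(coef(f2)[["dT"]], coef(f1)[["dT"]] / k, tolerance = 1e-3)
  expect_equal(coef(f2)[["dT2"]], coef(f1)[["dT2"]] / k^2,
               tolerance = 1e-3)
  expect_equal(coef(f2)[["dS"]], coef(f1)[["dS"]], tolerance = 1e-3)
})

test_that("BLUPs satisfy the shrinkage identities", {
  s <- sim_design(seed = 13, C = 6, years = 1985:2014, active = 1:6)
  f <- fit_mixed(s$design, active = 1:6)
  # D = 0 -> all BLUPs zero
  f0 <- fit_mixed(s$design, active = 1:6, random = FALSE)
  expect_true(all(ranef(f0) == 0))
  # direct formula b_c = D Z' V^{-1} (y - X beta) per region
  X <- s$design$X[, 1:6]
  for (r in levels(s$design$region)) {
    i <- s$design$region == r
    Z <- X[i, ]
    Vc <- Z %*% diag(f$D_diag) %*% t(Z) +
      f$sigma2 * f$phi[[r]] * diag(sum(i))
    bc <- diag(f$D_diag) %*% t(Z) %*%
      solve(Vc, s$design$y[i] - drop(Z %*% coef(f)))
    expect_equal(unname(ranef(f)[r, ]), drop(bc), tolerance = 1e-8)
  }
  # a region lying exactly on the fixed-effect surface has BLUP ~ 0
  p2 <- s$panel[s$panel$region %in% c("R01", "R02"), ]
  d2 <- build_design(p2)
  mu <- drop(d2$X[, 1:6] %*% coef(f)[1:6])
  d2$y <- mu
  st2 <- yieldclim:::yc_region_stats(d2$X[, 1:6], d2$y,
                                     droplevels(d2$region))
  ev <- yieldclim:::mm_eval_cpp(st2$A, st2$U, st2$s, st2$nv,
                                f$lambda, f$phi[1:2], FALSE, TRUE)
  # residuals against the fitted surface are zero, so BLUPs vanish
  expect_lt(max(abs(ev$blup)), 1e-6)
})

test_that("duplicating every region roughly halves coefficient variances", {
  s <- sim_design(seed = 14, C = 8, years = 1985:2014, active = c(1, 2, 4))
  f1 <- fit_mixed(s$design, active = c(1, 2, 4))
  p2 <- s$panel
  p2$region <- paste0(p2$region, "dup")
  pp <- rbind(s$panel, p2)
  f2 <- fit_mixed(build_design(pp), active = c(1, 2, 4))
  ratio <- diag(vcov(f2)) / diag(vcov(f1))
  expect_true(all(abs(ratio - 0.5) < 0.15))
})

test_that("information criteria follow the definitions", {
  s <- sim_design(seed = 15, C = 4, years = 1990:2014, active = c(1, 2, 4))
  f1 <- fit_mixed(s$design, active = c(1, 2), random = FALSE, het = FALSE)
  f2 <- fit_mixed(s$design, active = c(1, 2, 4), random = FALSE,
                  het = FALSE)
  ic1 <- information_criteria(f1)
  ic2 <- information_criteria(f2)
  n <- ic1[["n"]]
  expect_equal(ic1[["df"]] + 1, ic2[["df"]])
  expect_equal(
    (ic2[["BIC"]] + 2 * as.numeric(logLik(f2))) -
      (ic1[["BIC"]] + 2 * as.numeric(logLik(f1))),
    log(n))
  # ML fit counts random-effect and ratio parameters too
  fm <- fit_mixed(s$design, active = c(1, 2))
  expect_equal(attr(logLik(fm), "df"), 2 + 2 + 1 + (4 - 1))
})

test_that("wald tests: z/p relationship and joint consistency", {
  s <- sim_design(seed = 16, C = 4, years = 1990:2014, active = 1:6)
  f <- fit_mixed(s$design, active = 1:6)
  wt <- wald_tests(f, groups = list(inter = "dT.dS",
                                    quads = c("dT2", "dS2")))
  expect_equal(wt$table$p, 2 * pnorm(-abs(wt$table$z)))
  # a single-term joint test equals the squared-z chi-square test
  i <- match("dT.dS", wt$table$term)
  expect_equal(wt$joint$p[wt$joint$group == "inter"],
               pchisq(wt$table$z[i]^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(wt$joint$df, c(1, 2))
})

test_that("backward elimination respects marginality and finds signal", {
  # strong dT only: final mask keeps intercept + dT, and dT2/dS/dS2 go
  beta <- rep(0, 13)
  beta[2] <- -0.08
  s <- sim_design(seed = 17, C = 10, years = 1961:2014, active = 2,
                  beta = beta, D = rep(0, 13))
  f <- backward_eliminate(s$design, active = 1:6, engine = "mixed")
  expect_true(all(c(1, 2) %in% f$active))
  expect_false(any(c(5, 6) %in% f$active))
  tr <- attr(f, "trace")
  expect_true(nrow(tr) >= 3)
  # dropped terms never violate marginality at the step they were dropped
  act <- 1:6
  for (i in seq_len(nrow(tr))) {
    col <- match(tr$dropped[i], yc_terms())
    expect_true(col %in% yieldclim:::yc_removable(act))
    act <- setdiff(act, col)
  }
})

test_that("agreement with nlme::lme on random slopes + variance ratios", {
  skip_if_not_installed("nlme")
  s <- sim_design(seed = 19, C = 6, years = 1975:2014, active = c(1, 2, 4))
  f <- fit_mixed(s$design, active = c(1, 2, 4))
  dat <- data.frame(y = s$design$y, dT = s$design$X[, 2],
                    dS = s$design$X[, 4], region = s$design$region)
  lf <- nlme::lme(y ~ dT + dS,
                  random = list(region = nlme::pdDiag(~ dT + dS)),
                  weights = nlme::varIdent(form = ~ 1 | region),
                  data = dat, method = "ML",
                  control = nlme::lmeControl(opt = "optim",
                                             maxIter = 200,
                                             msMaxIter = 200))
  expect_lt(max(abs(coef(f) - nlme::fixef(lf))), 1e-4)
  # both climb the same likelihood; ours must not be worse
  expect_gte(f$loglik, as.numeric(logLik(lf)) - 1e-6)
  expect_lt(abs(f$loglik - as.numeric(logLik(lf))), 0.01)
})

test_that("singular designs fail with a named-column diagnosis", {
  s <- sim_design(seed = 20, C = 3, years = 2000:2014, active = 1:6)
  p <- s$panel
  p$dSPEI <- p$dTemp          # dS duplicates dT
  p$lag_dSPEI <- p$lag_dTemp
  expect_error(fit_mixed(build_design(p), active = c(1, 2, 4)),
               "singular design.*dS")
})
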