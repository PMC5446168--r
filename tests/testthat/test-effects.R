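# Quantiles, the exp-1 percent transform and conditioned effect curves.

test_that("empirical quantiles behave as stated", {
  set.seed(901)
  x <- rnorm(10000)
  p <- data.frame(region = "A", crop = "c", year = seq_along(x),
                  dYield = 0, dTemp = x, dSPEI = x,
                  lag_dTemp = 0, lag_dSPEI = 0)
  q <- climate_quantiles(p, "dSPEI")
  expect_lt(abs(q[[1]] + 1.645), 0.06)
  expect_lt(abs(q[[1]] + q[[3]]), 0.1)   # symmetric sample
  # odd-length sample: the median is the middle element
  xs <- c(5, 1, 9, 3, 7)
  ps <- p[1:5, ]
  ps$dTemp <- xs
  expect_equal(unname(climate_quantiles(ps, "dTemp", probs = 0.5,
                                        min_obs = 5)), 5)
  expect_error(climate_quantiles(p[1:10, ], "dTemp"), "too few")
})

test_that("per-region scope restricts the sample", {
  p <- data.frame(region = rep(c("A", "B"), each = 25), crop = "c",
                  year = 1:50, dYield = 0,
                  dTemp = c(1:25, 101:125), dSPEI = 0,
                  lag_dTemp = 0, lag_dSPEI = 0)
  qa <- climate_quantiles(p, "dTemp", probs = 0.5, scope = "A")
  expect_equal(unname(qa), 13)
})

test_that("the percent transform is exact algebra", {
  # eta = -0.1 -> -9.516%; zero model -> 0% with CI containing 0
  f <- toy_fit(beta = c(0, -0.1), active = c(1, 2))
  e <- effect_at(f, dT = 1)
  expect_equal(e$effect, 100 * (exp(-0.1) - 1), tolerance = 1e-10)
  expect_equal(e$effect, -9.516258, tolerance = 1e-4)
  f0 <- toy_fit(beta = c(0, 0, 0), V = diag(1e-4, 3), active = c(1, 2, 4))
  e0 <- effect_at(f0, dT = 2, dS = -1)
  expect_equal(e0$effect, 0)
  expect_lt(e0$lo, 0)
  expect_gt(e0$hi, 0)
})

test_that("delta-method CI matches a hand-assembled oracle", {
  set.seed(902)
  V <- crossprod(matrix(rnorm(9), 3))
  beta <- c(0.01, -0.03, 0.02)
  f <- toy_fit(beta = beta, V = V, active = c(1, 2, 4))
  dT <- 0.7; dS <- -1.2
  cc <- c(0, dT, dS)   # intercept excluded
  eta <- sum(cc * beta)
  se <- sqrt(drop(t(cc) %*% V %*% cc))
  e <- effect_at(f, dT = dT, dS = dS)
  expect_equal(e$eta, eta, tolerance = 1e-10)
  expect_equal(e$se, se, tolerance = 1e-10)
  expect_equal(e$lo, 100 * (exp(eta - 1.959964 * se) - 1),
               tolerance = 1e-6)
})

test_that("intercept is excluded: zero anomalies give a 0% effect", {
  f <- toy_fit(beta = c(0.3, -0.05, 0.02), active = c(1, 2, 4))
  expect_equal(effect_at(f)$effect, 0)
})

test_that("interaction-only model: flat at median, sloped at wet quantile", {
  set.seed(903)
  n <- 400
  p <- data.frame(region = "A", crop = "c", year = 1:n, dYield = 0,
                  dTemp = rnorm(n), dSPEI = rnorm(n),
                  lag_dTemp = 0, lag_dSPEI = 0)
  gamma1 <- -0.04
  f <- toy_fit(beta = c(0, gamma1), active = c(1, 6))
  flat <- effect_curve(f, x = "dT", panel = p, cond = "dS",
                       cond_value = 0)
  expect_true(all(abs(flat$effect) < 1e-12))
  q95 <- unname(climate_quantiles(p, "dSPEI", probs = 0.95))
  wet <- effect_curve(f, x = "dT", panel = p, cond = "dS",
                      cond_prob = 0.95)
  expect_equal(wet$effect, 100 * (exp(gamma1 * q95 * wet$x) - 1),
               tolerance = 1e-10)
  # line through the origin with the slope sign of gamma1 (given q95 > 0)
  expect_equal(wet$effect[which.min(abs(wet$x))],
               100 * (exp(gamma1 * q95 * wet$x[which.min(abs(wet$x))]) - 1))
  expect_lt(wet$effect[length(wet$x)], 0)
})

test_that("model with only dS active gives a flat dT curve", {
  set.seed(904)
  p <- data.frame(region = "A", crop = "c", year = 1:300, dYield = 0,
                  dTemp = rnorm(300), dSPEI = rnorm(300),
                  lag_dTemp = 0, lag_dSPEI = 0)
  f <- toy_fit(beta = c(0, 0.05), active = c(1, 4))
  cur <- effect_curve(f, x = "dT", panel = p, cond = "dS",
                      cond_value = 0)
  expect_true(all(cur$effect == 0))
})

test_that("no interactions: temperature curve identical at all SPEI quantiles", {
  s <- sim_design(seed = 90, C = 5, years = 1985:2014, active = c(1, 2, 4))
  f <- fit_mixed(s$design, active = c(1, 2, 3, 4, 5))
  cs <- lapply(c(0.05, 0.5, 0.95), function(pr)
    effect_curve(f, x = "dT", panel = s$panel, cond = "dS",
                 cond_prob = pr))
  expect_equal(cs[[1]]$effect, cs[[2]]$effect, tolerance = 1e-12)
  expect_equal(cs[[2]]$effect, cs[[3]]$effect, tolerance = 1e-12)
})

test_that("curves at SPEI quantiles coincide at dT=0 iff no pure-dS terms", {
  set.seed(905)
  p <- data.frame(region = "A", crop = "c", year = 1:300, dYield = 0,
                  dTemp = rnorm(300), dSPEI = rnorm(300),
                  lag_dTemp = 0, lag_dSPEI = 0)
  # interaction only: all conditioning curves pass through 0 at dT=0
  fi <- toy_fit(beta = c(0, -0.04), active = c(1, 6))
  # with a pure dS term the conditioning shifts the curve at dT=0
  fs <- toy_fit(beta = c(0, 0.05, -0.04), active = c(1, 4, 6))
  # evaluate exactly at dT = 0 via effect_at
  q05 <- unname(climate_quantiles(p, "dSPEI", probs = 0.05))
  q95 <- unname(climate_quantiles(p, "dSPEI", probs = 0.95))
  expect_equal(effect_at(fi, dT = 0, dS = q05)$effect, 0)
  expect_equal(effect_at(fi, dT = 0, dS = q95)$effect, 0)
  expect_true(abs(effect_at(fs, dT = 0, dS = q05)$effect -
                    effect_at(fs, dT = 0, dS = q95)$effect) > 1)
})

test_that("monotone transform preserves the ordering of linear predictors", {
  etas <- c(-0.2, -0.05, 0, 0.1)
  eff <- 100 * (exp(etas) - 1)
  expect_equal(order(eff), order(etas))
})

test_that("CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(10, 40), function(C) {
    s <- sim_design(seed = 91, C = C, years = 1961:2014,
                    active = c(1, 2, 4), D = rep(0, 13),
                    phi_range = c(1, 1))
    f <- fit_mixed(s$design, active = c(1, 2, 4), random = FALSE,
                   het = FALSE)
    e <- effect_at(f, dT = 1)
    e$hi - e$lo
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
})

test_that("extrapolation beyond 3x the data range warns", {
  s <- sim_design(seed = 92, C = 3, years = 1995:2014, active = c(1, 2))
  f <- fit_mixed(s$design, active = c(1, 2), random = FALSE, het = FALSE)
  big <- 4 * max(abs(s$design$ranges[, "dT"]))
  expect_warning(effect_at(f, dT = big), "extrapolation")
})
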