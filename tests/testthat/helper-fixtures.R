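# Shared fixtures: small simulated datasets with known truth, a
# brute-force likelihood oracle, and a hand-made toy fit for the effect
# algebra.

# Simulated anomaly panel + design at configurable scale.
sim_design <- function(seed = 1, C = 6, years = 1990:2014, active = 1:6,
                       beta = NULL, D = NULL, sigma2 = NULL,
                       phi_range = c(0.5, 2), noise = 1, ...) {
  cfg <- syn_config(n_regions = C, years = years, seed = seed,
                    phi_range = phi_range, ...)
  tr <- gen_truth(cfg, active = active, beta = beta, D_diag = D,
                  sigma2 = sigma2)
  sim <- gen_yield_panel(tr, cfg, noise = noise)
  list(cfg = cfg, truth = tr, sim = sim, panel = sim$truth_panel,
       design = build_design(sim$truth_panel))
}

# Independent likelihood oracle: assemble the full joint covariance
# matrix across all observations and evaluate the Gaussian log density
# directly (no block shortcuts).
brute_loglik <- function(design, beta, D, s2, phi, active) {
  X <- design$X[, active, drop = FALSE]
  y <- design$y
  reg <- droplevels(design$region)
  n <- length(y)
  V <- matrix(0, n, n)
  for (r in levels(reg)) {
    i <- which(reg == r)
    V[i, i] <- X[i, , drop = FALSE] %*% diag(D, length(D)) %*%
      t(X[i, , drop = FALSE]) +
      s2 * phi[match(r, levels(reg))] * diag(length(i))
  }
  r <- y - drop(X %*% beta)
  R <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) +
            sum(backsolve(R, r, transpose = TRUE)^2))
}

# Minimal single-region fit object with prescribed coefficients and
# covariance, for exact algebraic checks of the effect transform.
toy_fit <- function(beta, V = NULL, active = seq_along(beta) ) {
  stopifnot(length(active) == length(beta))
  nm <- yc_terms()[active]
  if (is.null(V)) V <- matrix(0, length(beta), length(beta))
  dimnames(V) <- list(nm, nm)
  rng <- matrix(c(-2, 2), 2, 4)
  colnames(rng) <- c("dT", "dS", "lagT", "lagS")
  structure(list(coefficients = setNames(beta, nm), vcov = V,
                 active = active, design = list(ranges = rng)),
            class = "yield_cm")
}

# Tiny hand-written anomaly panel (2 regions x 4 years).
toy_panel <- function() {
  data.frame(
    region = rep(c("A", "B"), each = 4), crop = "maize",
    year = rep(2001:2004, 2),
    dYield = c(0.1, -0.1, 0.05, -0.05, 0.2, -0.2, 0.1, -0.1),
    dTemp = c(0.5, -0.5, 1, -1, 0.3, -0.3, 0.6, -0.6),
    dSPEI = c(1, -1, 0.5, -0.5, 0.8, -0.8, 0.4, -0.4),
    lag_dTemp = c(NA, 0.5, -0.5, 1, NA, 0.3, -0.3, 0.6),
    lag_dSPEI = c(NA, 1, -1, 0.5, NA, 0.8, -0.8, 0.4))
}
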