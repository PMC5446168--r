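# Measurement-error robustness study: inject noise scaled to each
# series' own standard deviation into the detrended log yields, refit the
# selected model without re-selection, and track the significance of the
# highest-order retained terms.

#' Add relative measurement noise to detrended log yields
#'
#' Per region-crop series, adds `N(0, (fraction * sd_series)^2)` noise to
#' `dYield` only -- the same percent relative error for every series;
#' climate columns are untouched and the panel is not re-detrended.
#'
#' @param panel An `"anomaly_panel"`.
#' @param fraction Noise fraction of the series sd, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The panel with noisy `dYield`.
#' @export
add_noise <- function(panel, fraction, seed) {
  if (fraction < 0 || fraction > 0.5)
    stop("fraction must lie in [0, 0.5]")
  if (fraction == 0) return(panel)
  set.seed(as.integer(seed))
  key <- interaction(panel$region, panel$crop, drop = TRUE)
  sds <- ave(panel$dYield, key, FUN = function(x) sd(x, na.rm = TRUE))
  panel$dYield <- panel$dYield + rnorm(nrow(panel), 0, fraction * sds)
  panel
}

#' Highest-order retained terms
#'
#' Returns all retained terms of maximal polynomial order: interaction
#' terms outrank pure quadratics, which outrank linear terms; among
#' interactions higher total degree wins (so dT2.dS2 dominates
#' everything). The result is a joint-test group.
#'
#' @param active Active mask (intercept-only masks are an error).
#' @return Integer vector of term columns.
#' @export
highest_order_terms <- function(active) {
  active <- setdiff(sort(unique(as.integer(active))), 1L)
  if (!length(active)) stop("mask retains only the intercept")
  r <- yc_term_rank()[active]
  active[r == max(r)]
}

yc_subseed <- function(master, frac_i, rep_j) {
  as.integer((as.double(master) + 100003 * frac_i + 1009 * rep_j) %%
               2147483629)
}

#' Noise-injection significance simulation
#'
#' For each noise fraction and replication: derive a deterministic
#' sub-seed from the master seed, inject noise into the detrended log
#' yields, refit the baseline model (same active mask -- the model is
#' refit, not re-selected), and record the p-value of the highest-order
#' retained term group (joint Wald test for multi-term groups, the
#' per-coefficient test for single terms).
#'
#' @param panel Clean `"anomaly_panel"`.
#' @param active Active mask of the baseline model, selected once on the
#'   clean data.
#' @param fractions Noise fractions (default `seq(0.01, 0.5, by = 0.01)`).
#' @param reps Replications per fraction (default 100).
#' @param seed Master seed.
#' @param engine `"country"` (OLS refits) or `"mixed"`.
#' @param region Region for the country engine.
#' @param refit_variance For the mixed engine, refit variance parameters
#'   on each noisy dataset (default `TRUE`); with `FALSE` they are frozen
#'   at the clean-data estimates and only the GLS step is redone.
#' @return Object of class `"noise_sim"`: data frame `draws` (fraction,
#'   rep, p, converged), the binned `summary` (shares of p > 0.1,
#'   0.05-0.1, 0.01-0.05, <= 0.01 per fraction), the term `group`, seeds.
#' @export
run_noise_sim <- function(panel, active, fractions = seq(0.01, 0.5, 0.01),
                          reps = 100, seed = 1L,
                          engine = c("country", "mixed"), region = NULL,
                          refit_variance = TRUE) {
  engine <- match.arg(engine)
  group <- highest_order_terms(active)
  gname <- paste(yc_terms()[group], collapse = "+")
  clean_fit <- NULL
  p_of <- function(pan) {
    d <- build_design(pan)
    fit <- if (engine == "country") {
      if (!is.null(region)) d <- yc_design_region(d, region)
      fit_country(d, active = active)
    } else if (refit_variance || is.null(clean_fit)) {
      fit_mixed(d, active = active)
    } else {
      yc_refit_frozen(clean_fit, d)
    }
    if (engine == "mixed" && is.null(clean_fit)) clean_fit <<- fit
    wt <- wald_tests(fit, groups = setNames(list(yc_terms()[group]),
                                            gname))
    wt$joint$p[1]
  }
  if (engine == "mixed" && !refit_variance) p_clean <- p_of(panel)
  draws <- expand.grid(rep = seq_len(reps), fraction = fractions,
                       KEEP.OUT.ATTRS = FALSE)[, c("fraction", "rep")]
  draws$p <- NA_real_
  draws$converged <- TRUE
  for (k in seq_len(nrow(draws))) {
    fi <- match(draws$fraction[k], fractions)
    sub <- yc_subseed(seed, fi, draws$rep[k])
    noisy <- add_noise(panel, draws$fraction[k], sub)
    draws$p[k] <- tryCatch(p_of(noisy), error = function(e) {
      draws$converged[k] <<- FALSE
      NA_real_
    })
  }
  bins <- c(0, 0.01, 0.05, 0.1, 1)
  labs <- c("p<=0.01", "0.01-0.05", "0.05-0.1", "p>0.1")
  summ <- do.call(rbind, lapply(fractions, function(fr) {
    p <- draws$p[draws$fraction == fr]
    ok <- !is.na(p)
    sh <- as.vector(table(cut(p[ok], bins, labels = labs,
                              include.lowest = TRUE))) / sum(ok)
    data.frame(fraction = fr, bin = labs, share = sh,
               n_missing = sum(!ok))
  }))
  structure(list(draws = draws, summary = summ, group = group,
                 group_name = gname, fractions = fractions, reps = reps,
                 seed = seed, engine = engine),
            class = "noise_sim")
}

#' @export
print.noise_sim <- function(x, ...) {
  cat(sprintf(
    "Noise simulation: term group %s, %d fractions x %d reps (%s)\n",
    x$group_name, length(x$fractions), x$reps, x$engine))
  m <- tapply(x$draws$p, x$draws$fraction, mean, na.rm = TRUE)
  cat("mean p by fraction:\n")
  print(signif(m, 3))
  invisible(x)
}

#' Stacked-bar summary of the noise simulation
#'
#' Shares of the four p-value bands per noise fraction.
#'
#' @param x A `"noise_sim"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the share matrix.
#' @export
plot.noise_sim <- function(x, ...) {
  s <- x$summary
  m <- t(vapply(split(s, s$fraction),
                function(d) d$share[match(c("p<=0.01", "0.01-0.05",
                                            "0.05-0.1", "p>0.1"), d$bin)],
                numeric(4)))
  graphics::barplot(t(m), names.arg = format(x$fractions),
                    col = c("grey20", "grey45", "grey70", "grey90"),
                    border = NA, xlab = "noise fraction of series sd",
                    ylab = "share of replications",
                    legend.text = c("p<=0.01", "0.01-0.05", "0.05-0.1",
                                    "p>0.1"), ...)
  invisible(m)
}

# Refit only the GLS step at frozen variance parameters (used by the
# mixed-engine noise simulation with refit_variance = FALSE).
yc_refit_frozen <- function(fit, design) {
  X <- design$X[, fit$active, drop = FALSE]
  st <- yc_region_stats(X, design$y, droplevels(design$region))
  ev <- mm_eval_cpp(st$A, st$U, st$s, st$nv, fit$lambda, fit$phi,
                    fit$method == "REML", FALSE)
  out <- fit
  out$coefficients <- setNames(drop(ev$beta), colnames(X))
  V <- ev$sigma2 * solve(ev$H)
  dimnames(V) <- list(colnames(X), colnames(X))
  out$vcov <- V
  out$sigma2 <- ev$sigma2
  out$loglik <- ev$loglik
  out$design <- design
  out
}
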