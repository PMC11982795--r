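# Unit-level checks of the fitting machinery on reduced problems; the
# full-scale 20-replicate parameter-recovery study lives in
# test-acceptance.R.

truth <- population_params(1.2, 1.5, 0.29, -0.22, -0.83, 0.08)

quick_fit <- function(sim_seed, fit_seed, n_iterations = 800L,
                      n_chains = 2L, days = 60L, ...) {
  cfg <- simulation_config(n_plants = 3L, seasons_per_plant = c(2L, 1L, 1L),
                           days_per_season = days, seed = sim_seed)
  study <- simulate_daily_records(cfg)
  fit <- quiet(fit_posterior(study$records,
                             fit_config(n_chains = n_chains,
                                        n_iterations = n_iterations,
                                        seed = fit_seed, ...)))
  list(study = study, fit = fit)
}

test_that("a reduced fit lands near the generating parameters", {
  qf <- quick_fit(301, 302, n_iterations = 1000L, n_chains = 2L,
                  days = 80L)
  s <- summary(qf$fit)
  est <- stats::setNames(s$mean, s$parameter)
  expect_lt(abs(est["alpha"] - 0.29), 0.08)
  expect_lt(abs(est["psi_threshold"] + 0.83), 0.25)
  expect_lt(abs(est["sigma"] - 0.08), 0.015)
  expect_lt(abs(est["beta"] + 0.22), 0.15)
  expect_lt(max(qf$fit$rhat), 1.1)  # loose gate at this chain length
  ci <- posterior_interval(qf$fit)
  expect_true(ci["sigma", "lower"] < 0.08 && 0.08 < ci["sigma", "upper"])
})

test_that("no-threshold data collapses the changepoint effect to nothing", {
  cfg <- simulation_config(n_plants = 3L, seasons_per_plant = c(1L, 1L, 1L),
                           days_per_season = 70L, seed = 41,
                           params = population_params(1.2, 1.5, alpha = 0,
                                                      beta = 0,
                                                      psi_threshold = -0.83,
                                                      sigma = 0.08))
  study <- simulate_daily_records(cfg)
  fit <- quiet(fit_posterior(study$records,
                             fit_config(n_chains = 2L, n_iterations = 800L,
                                        seed = 42)))
  # when the data carry no changepoint, the threshold drifts to (or below)
  # the driest observed soil and the rates lose leverage; the identified
  # quantity is the *effective* change over the observed soil range, which
  # must concentrate at zero
  al <- as.vector(fit$draws[, , "alpha"])
  be <- as.vector(fit$draws[, , "beta"])
  th <- as.vector(fit$draws[, , "psi_threshold"])
  span <- pmax(0, th - min(study$records$psi_soil_day))
  theta_reduction <- 1 - exp(-al * span)
  lambda_factor <- exp(-be * span)
  expect_lt(median(theta_reduction), 0.05)
  expect_lt(stats::quantile(theta_reduction, 0.9), 0.15)
  expect_lt(abs(median(lambda_factor) - 1), 0.15)
})

test_that("LOO prefers the changepoint model on threshold data", {
  qf <- quick_fit(51, 52)
  fit_null <- quiet(fit_posterior(qf$study$records,
                                  fit_config(n_chains = 2L,
                                             n_iterations = 800L,
                                             seed = 53, threshold = FALSE)))
  loo_full <- quiet(compute_loo(qf$fit))
  loo_null <- quiet(compute_loo(fit_null))
  expect_gt(loo_full$elpd_loo, loo_null$elpd_loo + 3 * loo_null$se)
  expect_false("psi_threshold" %in% dimnames(fit_null$draws)[[3]])
})

test_that("seeded fits are bitwise reproducible", {
  qf1 <- quick_fit(61, 62, n_iterations = 300L, days = 30L)
  qf2 <- quick_fit(61, 62, n_iterations = 300L, days = 30L)
  expect_identical(qf1$fit$draws, qf2$fit$draws)
  expect_identical(summary(qf1$fit), summary(qf2$fit))
})

test_that("a single plant-year level degrades to a fixed-effects fit", {
  cfg <- simulation_config(n_plants = 1L, seasons_per_plant = 1L,
                           days_per_season = 50L, seed = 71)
  study <- simulate_daily_records(cfg)
  expect_warning(fit <- suppressMessages(
    fit_posterior(study$records, fit_config(n_chains = 2L,
                                            n_iterations = 400L,
                                            seed = 72))),
    "one plant-year level")
  expect_false(fit$hierarchical)
  expect_false(any(grepl("^u_", dimnames(fit$draws)[[3]])))
})

test_that("posterior-predictive coverage has the right degenerate limits", {
  S <- 200; n <- 50
  y <- rnorm(n)
  base <- list(mu = matrix(y + 0.3, S, n, byrow = TRUE),
               data = list(y = y))
  class(base) <- "psi_fit"
  # zero-width intervals away from the data: coverage 0
  base$draws <- array(0, dim = c(S, 1, 1), dimnames = list(NULL, NULL, "sigma"))
  expect_equal(ppc_coverage(base), 0)
  # essentially infinite width: coverage 1
  base$draws[] <- 1e6
  expect_equal(ppc_coverage(base), 1)
})

test_that("residuals show no per-plant shift on well-specified data", {
  qf <- quick_fit(81, 82)
  d <- quiet(diagnostics_report(qf$fit, seed = 82))
  rb <- d$residuals_by_plant
  expect_true(all(abs(rb$mean_resid) < 0.03))
  expect_lt(diff(range(rb$mean_abs_resid)), 0.03)
  expect_true(d$ppc_coverage_95 > 0.9 && d$ppc_coverage_95 <= 1)
  expect_lte(abs(d$loo_r2 - d$bayes_r2), 0.03)  # optimism gap stays small
})
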