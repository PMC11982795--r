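p_paper <- population_params(theta0 = 1, lambda0 = -log(0.05) / 1.94,
                             alpha = 0.29, beta = -0.22,
                             psi_threshold = -0.83, sigma = 0.08)

test_that("asymptote and curvature follow the changepoint forms", {
  # at the threshold: exactly the hydrated values (branch boundary)
  expect_equal(theta_at(-0.83, p_paper), 1)
  expect_equal(lambda_at(-0.83, p_paper), p_paper$lambda0)
  # direct evaluation at -4 MPa: >50% collapse of the asymptote
  expect_equal(theta_at(-4, p_paper), exp(-0.29 * (4 - 0.83)))
  expect_equal(theta_at(-4, p_paper), 0.3988, tolerance = 1e-4)
  expect_gt(1 - theta_at(-4, p_paper), 0.5)
  # curvature doubles (beta < 0 means lambda increases as soil dries)
  expect_equal(lambda_at(-4, p_paper) / p_paper$lambda0, 2.0085,
               tolerance = 1e-4)
  # rates zero: flat in soil water potential
  p0 <- population_params(1, 1.5, alpha = 0, beta = 0,
                          psi_threshold = -0.83)
  expect_equal(theta_at(c(0, -2, -6), p0), rep(1, 3))
  expect_equal(lambda_at(c(0, -2, -6), p0), rep(1.5, 3))
})

test_that("mean surface saturates, stays continuous and positive", {
  expect_equal(mean_delta_psi(0, 0, p_paper), 0)
  # 95% of the asymptote at 1.94 kPa by construction of lambda0
  expect_equal(mean_delta_psi(1.94, 0, p_paper), 0.95)
  # composition below threshold, against the two closed forms above
  expect_equal(mean_delta_psi(2, -4, p_paper),
               0.3988 * (1 - exp(-2.0085 * p_paper$lambda0 * 2)),
               tolerance = 1e-3)
  expect_equal(mean_delta_psi(2, -4, p_paper), 0.398, tolerance = 1e-3)
  # continuity at the threshold from both sides
  eps <- 1e-9
  for (v in c(0.5, 2, 4)) {
    expect_equal(mean_delta_psi(v, -0.83 - eps, p_paper),
                 mean_delta_psi(v, -0.83 + eps, p_paper),
                 tolerance = 1e-7)
  }
  expect_equal(theta_at(-0.83 - eps, p_paper), theta_at(-0.83 + eps, p_paper),
               tolerance = 1e-7)
  # monotone in VPD, bounded by theta, positive theta/lambda everywhere
  vg <- seq(0, 6, by = 0.05)
  for (ps in c(0, -0.83, -2, -3.6)) {
    mu <- mean_delta_psi(vg, ps, p_paper)
    expect_true(all(diff(mu) > 0))
    expect_true(all(mu <= theta_at(ps, p_paper)))
  }
  psg <- seq(0, -8, by = -0.1)
  expect_true(all(theta_at(psg, p_paper) > 0))
  expect_true(all(lambda_at(psg, p_paper) > 0))
  expect_true(all(diff(theta_at(psg, p_paper)) <= 0))  # non-increasing
  expect_true(all(diff(lambda_at(psg, p_paper)) >= 0)) # beta < 0
})

test_that("vpd_at_fraction inverts the saturating curve", {
  lam <- -log(0.05) / 1.94
  expect_equal(vpd_at_fraction(0.95, lam), 1.94)
  expect_equal(vpd_at_fraction(0.5, lam), 0.4489, tolerance = 1e-4)
  expect_equal(vpd_at_fraction(1e-9, lam), 0, tolerance = 1e-6)
  # exact inverse property
  for (f in c(0.1, 0.5, 0.9, 0.99)) {
    v <- vpd_at_fraction(f, lam)
    expect_equal(mean_delta_psi(v, 0, p_paper), f * theta_at(0, p_paper))
  }
  expect_error(vpd_at_fraction(1, lam), "in \\(0, 1\\)")
  expect_error(vpd_at_fraction(0.5, -1), "> 0")
})

test_that("log_likelihood equals brute-force per-point summation", {
  # one record with zero residual, sigma = 0.1
  p <- population_params(1.2, 1.5, 0.29, -0.22, -0.83, sigma = 0.1)
  re <- random_effects("P1:2022")
  mu <- mean_delta_psi(2, -1.5, p)
  one <- data.frame(delta_psi_max = mu, vpd_max_day = 2,
                    psi_soil_day = -1.5, level = "P1:2022")
  expect_equal(log_likelihood(one, p, re), -log(0.1) - 0.5 * log(2 * pi))
  expect_equal(log_likelihood(one, p, re), 1.3836, tolerance = 1e-4)
  # empty set
  expect_identical(log_likelihood(one[0, ], p, re), 0)
  # 10 random records with offsets: matches the oracle to 1e-12
  set.seed(7)
  re2 <- random_effects(c("A", "B"),
                        offsets = matrix(rnorm(4, 0, 0.2), 2),
                        sd_log_theta0 = 0.2, sd_log_lambda0 = 0.2,
                        correlation = 0.3)
  rec <- data.frame(delta_psi_max = runif(10, 0.1, 1.4),
                    vpd_max_day = runif(10, 0.2, 4),
                    psi_soil_day = runif(10, -3.5, 0),
                    level = sample(c("A", "B"), 10, replace = TRUE))
  expect_equal(log_likelihood(rec, p, re2), brute_loglik(rec, p, re2),
               tolerance = 1e-12)
  # unknown level
  rec$level[1] <- "C"
  expect_error(log_likelihood(rec, p, re2), "absent")
})

test_that("parameters serialize to unit-annotated JSON and back", {
  p <- population_params(1.2, 1.5, 0.29, -0.22, -0.83, 0.08)
  js <- params_to_json(p)
  expect_match(as.character(js), "theta0_mpa")
  expect_match(as.character(js), "lambda0_per_kpa")
  p2 <- params_from_json(as.character(js))
  expect_equal(unclass(p2), unclass(p))
  expect_error(population_params(-1, 1), "theta0")
})
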