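test_that("simulation is fully deterministic under its seed", {
  s1 <- simulate_daily_records(simulation_config(seed = 5))
  s2 <- simulate_daily_records(simulation_config(seed = 5))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$level_params, s2$level_params)
  cs1 <- simulate_climate_and_soil(simulation_config(seed = 6,
                                                     days_per_season = 30L))
  cs2 <- simulate_climate_and_soil(simulation_config(seed = 6,
                                                     days_per_season = 30L))
  expect_identical(cs1$climate$vpd, cs2$climate$vpd)
  expect_identical(cs1$soil, cs2$soil)
})

test_that("generated envelopes respect the reported climate and soil ranges", {
  cfg <- simulation_config(days_per_season = 120L, seed = 13)
  env <- simulate_climate_and_soil(cfg)
  expect_true(all(env$daily$vpd_max >= 0.34 - 1e-9))
  expect_true(all(env$daily$vpd_max <= 4.09 + 1e-9))
  expect_true(all(env$daily$temp_max >= 10 & env$daily$temp_max <= 32))
  expect_true(all(env$soil$psi_soil <= 0 & env$soil$psi_soil >= -3.6))
  # the raw series' daytime maxima come back out inside the envelope too
  cl_date <- date_of(env$climate$timestamp)
  by_day <- tapply(env$climate$vpd, cl_date, max)
  expect_true(all(by_day <= 4.09 + 1e-6))
})

test_that("soil drydown is monotone without rain and recharges with it", {
  dry <- simulation_config(n_plants = 1L, seasons_per_plant = 1L,
                           days_per_season = 80L, rain_prob = 0,
                           humid_night_prob = 0.5, seed = 17)
  env <- simulate_climate_and_soil(dry)
  expect_true(all(diff(env$soil$psi_soil) <= 1e-12))
  wet <- simulation_config(n_plants = 1L, seasons_per_plant = 1L,
                           days_per_season = 80L, rain_prob = 0.2, seed = 17)
  env2 <- simulate_climate_and_soil(wet)
  expect_true(any(diff(env2$soil$psi_soil) > 0.05))
})

test_that("a config without humid nights refuses to anchor soil", {
  cfg <- simulation_config(n_plants = 1L, seasons_per_plant = 1L,
                           days_per_season = 30L, rain_prob = 0,
                           humid_night_prob = 0, seed = 19)
  expect_error(simulate_climate_and_soil(cfg), "humid nights")
})

test_that("observations sit on the generating surface up to sigma", {
  cfg <- simulation_config(seed = 23)
  study <- simulate_daily_records(cfg)
  rec <- study$records
  # latent means recomputed from the stored level parameters (oracle path)
  lp <- study$level_params
  i <- match(rec$level, lp$level)
  p <- study$params
  d <- pmax(0, p$psi_threshold - rec$psi_soil_day)
  mu <- lp$theta0[i] * exp(-p$alpha * d) *
    (1 - exp(-lp$lambda0[i] * exp(-p$beta * d) * rec$vpd_max_day))
  expect_equal(rec$mu_true, mu, tolerance = 1e-12)
  resid <- rec$delta_psi_max - rec$mu_true
  expect_lt(abs(sd(resid) - p$sigma), 0.012)
  expect_lt(max(abs(resid)), 4.5 * p$sigma)
  # sigma = 0: observations equal the latent mean exactly
  s0 <- simulate_daily_records(simulation_config(
    seed = 23, params = population_params(1.2, 1.5, 0.29, -0.22, -0.83,
                                          sigma = 1e-12)))
  expect_equal(s0$records$delta_psi_max, s0$records$mu_true,
               tolerance = 1e-9)
})

test_that("the generative density peaks at the true parameters", {
  study <- simulate_daily_records(simulation_config(seed = 29))
  p <- study$params
  lp <- study$level_params
  re <- random_effects(lp$level,
                       offsets = cbind(log(lp$theta0 / p$theta0),
                                       log(lp$lambda0 / p$lambda0)))
  ll_true <- log_likelihood(study$records, p, re)
  perturb <- function(field, fac) {
    q <- unclass(p); q[[field]] <- q[[field]] * fac
    do.call(population_params, q)
  }
  for (field in c("theta0", "lambda0", "alpha", "sigma")) {
    expect_lt(log_likelihood(study$records, perturb(field, 1.25), re),
              ll_true, label = paste(field, "up"))
    expect_lt(log_likelihood(study$records, perturb(field, 0.8), re),
              ll_true, label = paste(field, "down"))
  }
})

test_that("humid nights in the raw series match the 0.05 kPa criterion", {
  cfg <- simulation_config(n_plants = 1L, seasons_per_plant = 1L,
                           days_per_season = 40L, seed = 37)
  env <- simulate_climate_and_soil(cfg)
  cl_date <- date_of(env$climate$timestamp)
  h <- hour_of_day(env$climate$timestamp)
  night_max <- tapply(env$climate$vpd[h < 4.5], cl_date[h < 4.5], max)
  flagged <- env$daily$humid_night[match(names(night_max),
                                         as.character(env$daily$date))]
  expect_identical(as.vector(night_max < 0.05), as.vector(flagged))
})

test_that("embedded pressure-chamber pairs refit the exact line", {
  study <- simulate_raw_series(simulation_config(
    n_plants = 2L, seasons_per_plant = c(1L, 1L), days_per_season = 40L,
    seed = 43))
  for (p in names(study$calibrations)) {
    truth <- study$calibrations[[p]]
    m <- fit_width_calibration(study$calibration[
      study$calibration$plant_id == p, ])
    expect_equal(m$slope, truth$slope, tolerance = 1e-10)
    expect_equal(m$intercept, truth$intercept, tolerance = 1e-7)
    expect_equal(m$r_squared, 1)
  }
  # widths invert back to the stem potentials that generated them
  cm <- study$calibrations[["P1"]]
  sel <- study$widths$plant_id == "P1"
  psi_back <- cm$slope * study$widths$width[sel] + cm$intercept
  expect_equal(psi_back, study$psi$psi_stem[study$psi$plant_id == "P1"],
               tolerance = 1e-10)
})

test_that("write_study emits the CSV dialects the loaders read", {
  study <- simulate_raw_series(simulation_config(
    n_plants = 1L, seasons_per_plant = 1L, days_per_season = 30L,
    seed = 47))
  dir <- file.path(tempdir(), "study_io")
  write_study(study, dir)
  cl <- quiet(read_climate_csv(file.path(dir, "climate.csv")))
  expect_equal(nrow(cl), nrow(study$climate))
  expect_equal(cl$vpd, study$climate$vpd, tolerance = 1e-9)
  w <- read_width_csv(file.path(dir, "widths.csv"))
  expect_identical(nrow(w), nrow(study$widths))
  p <- params_from_json(file.path(dir, "params_true.json"))
  expect_equal(p$psi_threshold, -0.83)
})
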