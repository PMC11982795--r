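test_that("exact lines are recovered exactly", {
  w <- c(1200, 1500, 1700, 2000)
  obs <- data.frame(plant_id = "P1", psi_bomb = 0.005 * (w - 2000),
                    width_at_time = w)
  m <- fit_width_calibration(obs)
  expect_equal(m$slope, 0.005)
  expect_equal(m$intercept, -10)
  expect_equal(m$r_squared, 1)
  # two points: line through both
  m2 <- fit_width_calibration(obs[c(1, 4), ])
  expect_equal(m2$slope, 0.005)
  expect_equal(m2$r_squared, 1)
  expect_identical(m2$n_points, 2L)
})

test_that("noisy calibration recovers truth within 3 closed-form SEs", {
  set.seed(41)
  w <- seq(1300, 2000, length.out = 20)
  noise <- rnorm(20, 0, 0.05)
  obs <- data.frame(plant_id = "P1",
                    psi_bomb = pmin(0.005 * (w - 2000) + noise, 0),
                    width_at_time = w)
  m <- fit_width_calibration(obs)
  # closed-form OLS standard errors, computed independently
  res <- obs$psi_bomb - (m$slope * w + m$intercept)
  s2 <- sum(res^2) / (20 - 2)
  se_slope <- sqrt(s2 / sum((w - mean(w))^2))
  se_int <- sqrt(s2 * (1 / 20 + mean(w)^2 / sum((w - mean(w))^2)))
  expect_lt(abs(m$slope - 0.005), 3 * se_slope)
  expect_lt(abs(m$intercept - (-10)), 3 * se_int)
  expect_gt(m$r_squared, 0.9)
})

test_that("degenerate and mismatched inputs error cleanly", {
  obs <- data.frame(plant_id = "P1", psi_bomb = c(-1, -2),
                    width_at_time = c(1500, 1500))
  expect_error(fit_width_calibration(obs), "degenerate")
  expect_error(fit_width_calibration(obs[0, ]), "at least 2")
  obs2 <- data.frame(plant_id = c("P1", "P2"), psi_bomb = c(-1, -2),
                     width_at_time = c(1500, 1600))
  expect_error(fit_width_calibration(obs2), "single plant")
})

test_that("apply_calibration is affine, clips drift, handles empty input", {
  m <- structure(list(plant_id = "P1", slope = 0.005, intercept = -10,
                      r_squared = 1, n_points = 4L),
                 class = "calibration_model")
  t0 <- as.POSIXct("2022-01-01", tz = "UTC")
  wid <- data.frame(timestamp = t0 + (0:3) * 900, plant_id = "P1",
                    width = c(1800, 1900, 2000, 2100))
  expect_message(out <- apply_calibration(wid, m), "clipped")
  expect_equal(out$psi_stem[1], -1)
  expect_equal(out$psi_stem[3], 0)       # boundary
  expect_true(out$flagged[3])            # boundary is flagged too
  expect_true(out$flagged[4])            # would be +0.5, clipped
  # affine: shifting widths by dw shifts psi by slope*dw exactly
  wid2 <- wid[1:2, ]; wid2$width <- wid2$width + 40
  out2 <- apply_calibration(wid2, m)
  expect_equal(out2$psi_stem, out$psi_stem[1:2] + 0.005 * 40)
  # round trip to machine precision
  w_back <- (out$psi_stem[1:2] - m$intercept) / m$slope
  expect_equal(w_back, wid$width[1:2], tolerance = 1e-12)
  # empty series and plant mismatch
  expect_identical(nrow(apply_calibration(wid[0, ], m)), 0L)
  wid$plant_id <- "P9"
  expect_error(apply_calibration(wid, m), "other plants")
})
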