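test_that("steady-state window is found on a plateau and rejected without", {
  cfg <- extraction_config()
  day <- plateau_day(plateau = -1.2, plateau_hours = c(12, 14))
  sun <- sunrise_sunset(as.Date("2022-01-10"))
  res <- find_steady_state_min(day, c(sun$sunrise, sun$sunset), cfg)
  expect_false(is.null(res))
  expect_equal(res$mean_psi, -1.2)
  expect_true(hour_of_day(res$t_mid) >= 12 && hour_of_day(res$t_mid) <= 14)
  expect_gte(res$n_points, 4L)
  expect_lte(res$n_points, 8L)
  # brute-force oracle: the best (lowest-mean) qualifying 2-h window
  h <- hour_of_day(day$timestamp)
  daypts <- day[h >= sun$sunrise & h <= sun$sunset, ]
  best <- Inf
  for (i in seq_len(nrow(daypts))) {
    w <- daypts$psi_stem[daypts$timestamp >= daypts$timestamp[i] - 3600 &
                           daypts$timestamp < daypts$timestamp[i] + 3600]
    if (length(w) >= 4 && (max(w) - min(w)) <= 0.05 * abs(mean(w))) {
      best <- min(best, mean(w))
    }
  }
  expect_equal(res$mean_psi, best)

  # monotone decline all day at ~16%/h relative change: no plateau
  mono <- day
  mono$psi_stem <- -0.1 * exp(hour_of_day(mono$timestamp) / 6)
  expect_null(find_steady_state_min(mono, c(sun$sunrise, sun$sunset), cfg))

  # constant day qualifies trivially
  const <- day; const$psi_stem <- -0.5
  res2 <- find_steady_state_min(const, c(sun$sunrise, sun$sunset), cfg)
  expect_equal(res2$mean_psi, -0.5)
})

test_that("predawn anchors obey the humid-night rule", {
  cfg <- extraction_config()
  day <- plateau_day()
  day$psi_stem[hour_of_day(day$timestamp) < 5] <- -0.4  # predawn plateau
  cl_ok <- as_climate(flat_climate_day(night_vpd = 0.02))
  anch <- select_predawn_anchors(day, cl_ok, cfg)
  expect_identical(nrow(anch), 1L)
  expect_equal(anch$psi_predawn, -0.4)
  expect_lt(anch$night_max_vpd, 0.05)

  # a single 0.06 kPa reading at 03:00 disqualifies the night
  bad <- flat_climate_day(night_vpd = 0.02)
  bad$vpd[hour_of_day(bad$timestamp) == 3] <- 0.06
  bad$rh <- 100 * (1 - bad$vpd / buck_svp(20))
  expect_error(select_predawn_anchors(day, as_climate(bad), cfg),
               "cannot be tracked")
})

test_that("soil interpolation is linear, exact at anchors, refuses outside", {
  t0 <- as.POSIXct("2022-01-01", tz = "UTC")
  anch <- data.frame(plant_id = "P1",
                     date = as.Date("2022-01-01") + c(0, 10),
                     timestamp = t0 + c(0, 10) * 86400,
                     psi_predawn = c(-0.2, -1.2))
  tr <- interpolate_soil_psi(anch, t0 + 5 * 86400)
  expect_equal(tr$psi_soil, -0.7)  # midpoint
  expect_equal(interpolate_soil_psi(anch, anch$timestamp)$psi_soil,
               anch$psi_predawn)   # exact at anchors
  # three anchors, hand-computed interior point
  anch3 <- data.frame(plant_id = "P1",
                      date = as.Date("2022-01-01") + c(0, 4, 10),
                      timestamp = t0 + c(0, 4, 10) * 86400,
                      psi_predawn = c(-0.2, -0.2, -1.4))
  expect_equal(interpolate_soil_psi(anch3, t0 + 7 * 86400)$psi_soil, -0.8)
  # monotone between anchors (order preserving)
  fine <- interpolate_soil_psi(anch3, t0 + seq(4, 10, by = 0.25) * 86400)
  expect_true(all(diff(fine$psi_soil) <= 0))
  # outside the span: dropped with a message
  expect_message(out <- interpolate_soil_psi(anch, t0 + 30 * 86400),
                 "outside the anchor span")
  expect_true(is.na(out$psi_soil))
  expect_error(interpolate_soil_psi(anch[1, ], t0), "at least 2")
})

test_that("daily records subtract soil minus steady minimum and log exclusions", {
  cfg <- extraction_config()
  dates <- as.Date("2022-01-10") + 0:3
  psi <- do.call(rbind, lapply(seq_along(dates), function(i) {
    d <- plateau_day(date = dates[i], plateau = -1.1, base = -0.3)
    d$psi_stem[hour_of_day(d$timestamp) < 5] <- -0.3
    d
  }))
  # day 2 has no plateau: steep relative decline through the whole day
  sel <- date_of(psi$timestamp) == dates[2] & hour_of_day(psi$timestamp) >= 6
  psi$psi_stem[sel] <- -0.1 * exp(hour_of_day(psi$timestamp[sel]) / 6)
  # day 4 exists only as a predawn closing anchor
  sel4 <- date_of(psi$timestamp) == dates[4]
  psi <- psi[!(sel4 & hour_of_day(psi$timestamp) >= 5), ]
  climate <- as_climate(do.call(rbind, lapply(dates, function(d)
    flat_climate_day(date = d, night_vpd = 0.02, day_vpd = 2))))
  anchors <- select_predawn_anchors(psi, climate, cfg)
  expect_identical(nrow(anchors), 4L)
  expect_equal(anchors$psi_predawn, rep(-0.3, 4))
  rec <- quiet(build_daily_records(psi, anchors, climate, cfg))
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$delta_psi_max, rep(-0.3 - (-1.1), 2))  # 0.8 MPa
  expect_equal(rec$vpd_max_day, rep(2, 2))
  counts <- attr(rec, "exclusions")
  expect_identical(unname(counts["retained"] + counts["no_steady_state"]),
                   length(dates))
  expect_identical(attr(rec, "excluded")$reason, rep("no_steady_state", 2))
})

test_that("diurnal slice filters the window and joins within 10 minutes", {
  day <- plateau_day()
  climate <- as_climate(flat_climate_day(day_vpd = 1.5))
  sl <- diurnal_window_slice(day, climate)
  expect_true(all(hour_of_day(sl$timestamp) >= 11 &
                    hour_of_day(sl$timestamp) <= 15))
  expect_true(all(sl$vpd == 1.5))
  # empty overlap
  sl0 <- diurnal_window_slice(day[hour_of_day(day$timestamp) < 9, ], climate)
  expect_identical(nrow(sl0), 0L)
  # offset cadence: climate shifted by 5 min still joins, 20 min does not
  cl5 <- climate; cl5$timestamp <- cl5$timestamp + 300
  expect_gt(nrow(diurnal_window_slice(day, cl5)), 0)
  cl20 <- climate[seq(1, nrow(climate), by = 8), ]  # 2-h cadence
  cl20$timestamp <- cl20$timestamp + 3000
  expect_lt(nrow(diurnal_window_slice(day, cl20)),
            nrow(diurnal_window_slice(day, climate)))
})
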