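# Shared fixtures, built in code at test time.

# one synthetic tree-day at 15-min cadence: decline to a plateau, recovery
plateau_day <- function(date = as.Date("2022-01-10"), plateau = -1.2,
                        plateau_hours = c(12, 14), base = -0.2,
                        cadence_min = 15) {
  t0 <- as.POSIXct(date, tz = "UTC")
  h <- seq(0, 24 - cadence_min / 60, by = cadence_min / 60)
  psi <- numeric(length(h))
  rise <- h < plateau_hours[1]
  fall <- h > plateau_hours[2]
  psi[rise] <- base + (plateau - base) * pmax(0, (h[rise] - 6) /
                                                (plateau_hours[1] - 6))
  psi[h >= plateau_hours[1] & h <= plateau_hours[2]] <- plateau
  psi[fall] <- plateau + (base - plateau) *
    pmin(1, (h[fall] - plateau_hours[2]) / 5)
  data.frame(plant_id = "P1", timestamp = t0 + h * 3600, psi_stem = psi)
}

# a small climate day with prescribed night and day VPD
flat_climate_day <- function(date = as.Date("2022-01-10"),
                             night_vpd = 0.02, day_vpd = 2,
                             cadence_min = 15) {
  t0 <- as.POSIXct(date, tz = "UTC")
  h <- seq(0, 24 - cadence_min / 60, by = cadence_min / 60)
  vpd <- ifelse(h >= 6 & h <= 20, day_vpd, night_vpd)
  # back out temp/rh consistent with the Buck formula at 20 degC
  es20 <- buck_svp(20)
  data.frame(timestamp = t0 + h * 3600, air_temp = 20,
             rh = 100 * (1 - vpd / es20), vpd = vpd)
}

as_climate <- function(df) {
  climate_series(df$timestamp, df$air_temp, df$rh)
}

# brute-force Gaussian log-likelihood, independent of log_likelihood()
brute_loglik <- function(records, p, re) {
  tot <- 0
  for (i in seq_len(nrow(records))) {
    lv <- as.character(records$level[i])
    o <- re$offsets[lv, ]
    ps <- records$psi_soil_day[i]
    dd <- max(0, p$psi_threshold - ps)
    th <- p$theta0 * exp(o[1]) * exp(-p$alpha * dd)
    la <- p$lambda0 * exp(o[2]) * exp(-p$beta * dd)
    m <- th * (1 - exp(-la * records$vpd_max_day[i]))
    r <- records$delta_psi_max[i] - m
    tot <- tot - 0.5 * log(2 * pi * p$sigma^2) - r^2 / (2 * p$sigma^2)
  }
  unname(tot)
}

# central-difference gradient for checking analytic gradients
num_grad <- function(f, q, h = 1e-6) {
  vapply(seq_along(q), function(i) {
    qp <- q; qm <- q
    qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
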