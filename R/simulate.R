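# Synthetic studies with known parameters: seasonal climate forcing, soil
# drydowns with rain recharge, and Delta-Psi observations generated from the
# changepoint model -- optionally rendered down to raw 15-30 min diurnal
# stem-water-potential / branchlet-width signals so the whole extraction
# pipeline can be exercised end to end.

#' Configuration of a synthetic study
#'
#' Defaults reproduce the monitored design: 4 trees, 1-3 growing seasons
#' each (7 plant-year levels, ~600 tree-days), daytime maximum VPD clipped
#' to the observed 0.34-4.09 kPa envelope, daytime temperature within
#' 10-32 degC, and soil drydowns from near 0 toward seasonal minima in the
#' -3.6..-1.2 MPa range with episodic rain recharge. True population
#' parameters default to the fitted posterior means for the rates and
#' threshold, with asymptote/curvature/noise chosen to match the reported
#' 95%-saturation VPD (~1.94 kPa) and observed Delta-Psi magnitudes.
#'
#' @param n_plants number of trees.
#' @param seasons_per_plant integer vector (length `n_plants`): growing
#'   seasons per tree; seasons are shared calendar years starting in
#'   `start_year`.
#' @param days_per_season tree-days simulated per season.
#' @param params true [population_params].
#' @param sd_log_theta0,sd_log_lambda0,re_correlation plant-year
#'   random-effect scales (log scale) and their correlation.
#' @param vpd_range daily maximum VPD envelope (kPa), clipped.
#' @param temp_range daytime maximum temperature envelope (degC).
#' @param psi_min_range range from which each plant-season's soil water
#'   potential floor is drawn (MPa).
#' @param drydown_rate exponential approach rate toward the seasonal floor
#'   (per day).
#' @param rain_prob daily probability of a recharge event.
#' @param humid_night_prob baseline probability of a humid (VPD < 0.05 kPa)
#'   night; nights on and immediately before rain days are always humid
#'   (synoptic humidity around frontal rain).
#' @param cadence_min raw-series cadence in minutes (15 or 30).
#' @param start_year first season's calendar year.
#' @param seed integer seed; every simulate_* call is fully determined by
#'   the config.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_plants = 4L,
                              seasons_per_plant = c(3L, 2L, 1L, 1L),
                              days_per_season = 86L,
                              params = population_params(
                                theta0 = 1.2, lambda0 = 1.5, alpha = 0.29,
                                beta = -0.22, psi_threshold = -0.83,
                                sigma = 0.08),
                              sd_log_theta0 = 0.10, sd_log_lambda0 = 0.15,
                              re_correlation = 0.3,
                              vpd_range = c(0.34, 4.09),
                              temp_range = c(10, 32),
                              psi_min_range = c(-3.6, -1.2),
                              drydown_rate = 0.025, rain_prob = 0.05,
                              humid_night_prob = 0.5, cadence_min = 15L,
                              start_year = 2021L, seed = 1L) {
  stopifnot(length(seasons_per_plant) == n_plants,
            all(seasons_per_plant >= 1L), days_per_season >= 10L,
            cadence_min %in% c(15L, 30L),
            vpd_range[1] > 0, vpd_range[2] <= 4.09 + 1e-9)
  structure(list(n_plants = as.integer(n_plants),
                 seasons_per_plant = as.integer(seasons_per_plant),
                 days_per_season = as.integer(days_per_season),
                 params = params, sd_log_theta0 = sd_log_theta0,
                 sd_log_lambda0 = sd_log_lambda0,
                 re_correlation = re_correlation,
                 vpd_range = vpd_range, temp_range = temp_range,
                 psi_min_range = psi_min_range,
                 drydown_rate = drydown_rate, rain_prob = rain_prob,
                 humid_night_prob = humid_night_prob,
                 cadence_min = as.integer(cadence_min),
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# site-level daily weather for one season (year): Tmax, dryness, Vmax,
# rain and humid-night indicators
sim_season_weather <- function(config, year) {
  D <- config$days_per_season
  dates <- as.Date(sprintf("%d-01-05", year)) + seq_len(D) - 1L
  seasonal <- sin(pi * (seq_len(D) - 0.5) / D)  # mid-season peak
  tlo <- config$temp_range[1]; thi <- config$temp_range[2]
  temp_max <- tlo + (thi - tlo) * (0.35 + 0.5 * seasonal) +
    stats::rnorm(D, 0, 2.0)
  temp_max <- pmin(pmax(temp_max, tlo), thi)
  dryfrac <- stats::plogis(stats::qlogis(0.25 + 0.35 * seasonal) +
                             stats::rnorm(D, 0, 0.6))
  vpd_max <- pmin(pmax(buck_svp(temp_max) * dryfrac, config$vpd_range[1]),
                  config$vpd_range[2])
  dryfrac <- vpd_max / buck_svp(temp_max)
  rain <- stats::runif(D) < config$rain_prob
  humid <- rain | c(rain[-1], FALSE) |
    stats::runif(D) < config$humid_night_prob
  data.frame(date = dates, year = year, temp_max = temp_max,
             dryfrac = dryfrac, vpd_max = vpd_max, rain = rain,
             humid_night = humid)
}

# per plant-season daily soil water potential: exponential drydown toward
# the seasonal floor, partial recharge on rain days
sim_soil <- function(config, weather) {
  floor_psi <- stats::runif(1, config$psi_min_range[1],
                            config$psi_min_range[2])
  D <- nrow(weather)
  psi <- numeric(D)
  prev <- -0.05
  r <- exp(-config$drydown_rate)
  for (d in seq_len(D)) {
    if (weather$rain[d]) prev <- prev * stats::runif(1, 0.05, 0.5)
    psi[d] <- floor_psi + (prev - floor_psi) * r
    prev <- psi[d]
  }
  pmax(psi, -3.6)
}

#' Simulate climate forcing and per-plant soil drydowns
#'
#' Generates the environmental layer of a synthetic study: site-level
#' daily weather per season (temperature, daily maximum VPD inside the
#' configured envelope, rain days, humid nights), the corresponding raw
#' microclimate series at the configured cadence, and a per-plant daily
#' soil water potential track.
#'
#' @param config a [simulation_config].
#' @return list with `daily` (site weather), `climate` (a
#'   [climate_series] over all seasons), and `soil` (data frame
#'   `plant_id`, `season`, `date`, `psi_soil`). Errors if the
#'   configuration yields no humid nights (predawn anchoring impossible).
#' @export
simulate_climate_and_soil <- function(config = simulation_config()) {
  set.seed(config$seed)
  env <- sim_environment(config)
  if (!any(env$weather$humid_night)) {
    stop("configuration produced no humid nights; soil cannot be anchored")
  }
  climate <- render_climate(env$weather, config)
  list(daily = env$weather, climate = climate, soil = env$soil)
}

# shared generation of weather + soil (assumes seed already set)
sim_environment <- function(config) {
  years <- config$start_year + seq_len(max(config$seasons_per_plant)) - 1L
  weather <- do.call(rbind, lapply(years, function(y)
    sim_season_weather(config, y)))
  soil <- list()
  for (p in seq_len(config$n_plants)) {
    for (s in seq_len(config$seasons_per_plant[p])) {
      w <- weather[weather$year == years[s], ]
      # predawn (midnight-knot) soil state; the continuous track the plant
      # experiences through the day is linear between consecutive knots, so
      # the midday (13:15, the steady-state window midpoint) value sits
      # 13.25/24 of the way to the next knot
      knots <- sim_soil(config, w)
      nxt <- c(knots[-1], knots[length(knots)])
      soil[[length(soil) + 1L]] <- data.frame(
        plant_id = sprintf("P%d", p), season = as.character(years[s]),
        date = w$date, psi_soil = knots,
        psi_midday = knots + (13.25 / 24) * (nxt - knots))
    }
  }
  list(weather = weather, soil = do.call(rbind, soil))
}

# diurnal bell with a quasi-flat top around 13:15 solar-ish time; quartic
# exponent keeps variation over the +-1 h window ~1%, well under the 5%
# steady-state tolerance, while decaying to ~0 before dawn and after dusk
diurnal_shape <- function(hour) exp(-((hour - 13.25) / 3)^4)

# wider daytime envelope used to blend the within-day soil drift into the
# stem signal: ~1 at midday; the sixth-power tail underflows to 0 before
# sunrise, so predawn stem water potential equals the midnight soil knot
# exactly (to the double-precision ulp)
daytime_blend <- function(hour) exp(-((hour - 13.25) / 4.5)^6)

# raw microclimate series from daily weather
render_climate <- function(weather, config) {
  step_h <- config$cadence_min / 60
  hours <- seq(0, 24 - step_h, by = step_h)
  s <- diurnal_shape(hours)
  rows <- vector("list", nrow(weather))
  for (d in seq_len(nrow(weather))) {
    tmax <- weather$temp_max[d]
    tmin <- max(tmax - 12, 2)
    temp <- tmin + (tmax - tmin) * s
    frac_night <- if (weather$humid_night[d]) 0.004 else 0.12
    frac <- frac_night + (weather$dryfrac[d] - frac_night) * s
    rows[[d]] <- data.frame(
      timestamp = as.POSIXct(weather$date[d], tz = "UTC") + hours * 3600,
      temp_c = temp, rh_pct = 100 * (1 - frac))
  }
  x <- do.call(rbind, rows)
  climate_series(x$timestamp, x$temp_c, x$rh_pct)
}

#' Simulate daily maximum Delta-Psi records from known parameters
#'
#' The generative direction of the regulation model: per plant-year level,
#' correlated log-scale offsets on (`theta0`, `lambda0`) are drawn; per
#' tree-day, the expected `delta_psi_max` is evaluated at that day's
#' (maximum VPD, soil water potential) and Gaussian residual noise is
#' added. The latent truth is kept alongside the observations.
#'
#' @param config a [simulation_config].
#' @return list of class `simulated_study`: `records` (ready for
#'   [fit_posterior], including latent `mu_true` and `psi_soil` truth),
#'   `level_params` (per-level true `theta0`/`lambda0`), `weather`,
#'   `soil`, `params`, `config`.
#' @export
simulate_daily_records <- function(config = simulation_config()) {
  set.seed(config$seed)
  env <- sim_environment(config)
  p <- config$params
  levels_df <- unique(env$soil[, c("plant_id", "season")])
  L <- nrow(levels_df)
  z <- matrix(stats::rnorm(2 * L), L)
  rho <- config$re_correlation
  u1 <- config$sd_log_theta0 * z[, 1]
  u2 <- config$sd_log_lambda0 * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  levels_df$level <- paste(levels_df$plant_id, levels_df$season, sep = ":")
  levels_df$theta0 <- p$theta0 * exp(u1)
  levels_df$lambda0 <- p$lambda0 * exp(u2)
  soil <- env$soil
  soil$level <- paste(soil$plant_id, soil$season, sep = ":")
  li <- match(soil$level, levels_df$level)
  wmatch <- match(soil$date, env$weather$date)
  vpd <- env$weather$vpd_max[wmatch]
  d <- pmax(0, p$psi_threshold - soil$psi_midday)
  th <- levels_df$theta0[li] * exp(-p$alpha * d)
  lam <- levels_df$lambda0[li] * exp(-p$beta * d)
  mu <- th * (1 - exp(-lam * vpd))
  obs <- pmax(mu + stats::rnorm(nrow(soil), 0, p$sigma), 0.02)
  records <- data.frame(plant_id = soil$plant_id, date = soil$date,
                        season = soil$season, level = soil$level,
                        delta_psi_max = obs, vpd_max_day = vpd,
                        psi_soil_day = soil$psi_midday, mu_true = mu)
  structure(list(records = records, level_params = levels_df,
                 weather = env$weather, soil = env$soil,
                 params = p, config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d plants, %d plant-year levels, %d tree-days%s\n",
    x$config$n_plants, nrow(x$level_params), nrow(x$records),
    if (!is.null(x$psi)) sprintf(", raw cadence %d min", x$config$cadence_min)
    else ""))
  invisible(x)
}

#' Simulate raw diurnal series (width, stem water potential, microclimate)
#'
#' Renders the daily study of [simulate_daily_records] down to raw
#' signals: a diurnal stem-water-potential curve whose midday plateau
#' (quasi-constant for > 2 h) equals the day's observed `delta_psi_max`
#' below soil water potential, equilibrating to soil water potential
#' before dawn; a consistent microclimate series whose daytime maximum VPD
#' equals the record's VPD covariate and whose humid nights sit below the
#' 0.05 kPa criterion; per-plant branchlet-width series obtained by
#' inverting known linear calibrations; and embedded pressure-chamber
#' calibration pairs lying exactly on those lines.
#'
#' @param config a [simulation_config].
#' @return a `simulated_study` with additional elements `climate`
#'   ([climate_series]), `psi` (true `psi_series`), `widths`
#'   (`timestamp`, `plant_id`, `width`), `calibration` (pressure-chamber
#'   pairs) and `calibrations` (the true per-plant lines).
#' @export
simulate_raw_series <- function(config = simulation_config()) {
  study <- simulate_daily_records(config)
  climate <- render_climate(study$weather, config)
  step_h <- config$cadence_min / 60
  hours <- seq(0, 24 - step_h, by = step_h)
  s <- diurnal_shape(hours)
  g <- daytime_blend(hours)
  rec <- study$records
  soil_key <- paste(study$soil$plant_id, study$soil$season, study$soil$date)
  knot <- study$soil$psi_soil[match(paste(rec$plant_id, rec$season, rec$date),
                                    soil_key)]
  day_slope <- (rec$psi_soil_day - knot) / (13.25 / 24)  # knot step per day
  psi_rows <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    t0 <- as.POSIXct(rec$date[i], tz = "UTC")
    soil_t <- knot[i] + day_slope[i] * (hours / 24) * g
    psi_rows[[i]] <- data.frame(
      plant_id = rec$plant_id[i], timestamp = t0 + hours * 3600,
      psi_stem = soil_t - rec$delta_psi_max[i] * s)
  }
  psi <- do.call(rbind, psi_rows)
  psi <- psi[order(psi$plant_id, psi$timestamp), ]
  rownames(psi) <- NULL
  class(psi) <- c("psi_series", "data.frame")

  plants <- sprintf("P%d", seq_len(config$n_plants))
  cal_models <- lapply(seq_along(plants), function(pi) {
    slope <- 0.004 + 0.0005 * pi      # MPa per micrometre
    intercept <- -slope * 2000        # width 2000 um <=> Psi = 0
    structure(list(plant_id = plants[pi], slope = slope,
                   intercept = intercept, r_squared = 1,
                   n_points = NA_integer_),
              class = "calibration_model")
  })
  names(cal_models) <- plants
  widths <- psi
  for (p in plants) {
    cm <- cal_models[[p]]
    sel <- widths$plant_id == p
    widths$width[sel] <- (widths$psi_stem[sel] - cm$intercept) / cm$slope
  }
  widths <- widths[, c("timestamp", "plant_id", "width")]

  # pressure-chamber pairs: midday points every ~15 d, exactly on the line
  cal_obs <- list()
  for (p in plants) {
    pp <- psi[psi$plant_id == p & hour_of_day(psi$timestamp) == 12, ]
    pick <- pp[seq(1, nrow(pp), by = 15), ]
    cm <- cal_models[[p]]
    cal_obs[[p]] <- data.frame(
      plant_id = p, timestamp = pick$timestamp,
      psi_bomb = pick$psi_stem,
      width_at_time = (pick$psi_stem - cm$intercept) / cm$slope)
  }
  study$climate <- climate
  study$psi <- psi
  study$widths <- widths
  study$calibration <- do.call(rbind, cal_obs)
  study$calibrations <- cal_models
  study
}

#' Write a synthetic study to disk in the pipeline's CSV dialects
#'
#' A raw-level study writes `climate.csv`, `widths.csv`,
#' `calibration.csv`, plus the ground truth (`records_true.csv`,
#' `params_true.json`); a daily-level study writes `records.csv` and the
#' truth files. The raw files are drop-in replacements for real study
#' inputs.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_t <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
  if (!is.null(study$climate)) {
    utils::write.csv(data.frame(timestamp = fmt_t(study$climate$timestamp),
                                temp_c = study$climate$air_temp,
                                rh_pct = study$climate$rh),
                     file.path(dir, "climate.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(timestamp = fmt_t(study$widths$timestamp),
                                plant_id = study$widths$plant_id,
                                width_um = study$widths$width),
                     file.path(dir, "widths.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(plant_id = study$calibration$plant_id,
                                timestamp = fmt_t(study$calibration$timestamp),
                                psi_bomb_mpa = study$calibration$psi_bomb,
                                width_um = study$calibration$width_at_time),
                     file.path(dir, "calibration.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  rec <- study$records
  utils::write.csv(data.frame(plant_id = rec$plant_id,
                              date = as.character(rec$date),
                              season = rec$season,
                              delta_psi_max_mpa = rec$delta_psi_max,
                              vpd_max_kpa = rec$vpd_max_day,
                              psi_soil_mpa = rec$psi_soil_day,
                              excluded_reason = ""),
                   file.path(dir,
                             if (is.null(study$climate)) "records.csv"
                             else "records_true.csv"),
                   row.names = FALSE, quote = FALSE)
  params_to_json(study$params, file.path(dir, "params_true.json"))
  invisible(dir)
}
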