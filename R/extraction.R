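# From diurnal stem water potential and microclimate to one steady-state
# daily maximum Delta-Psi record per tree-day.
#
# Conventions:
#  * "daytime" = sunrise..sunset from solar geometry at the site coordinates;
#  * "night"   = midnight..sunrise of the same date;
#  * the 2-h averaging window is half-open, [t - 1 h, t + 1 h), which yields
#    8 points at 15-min cadence and 4 at 30-min, matching the 4-8 points the
#    steady-state definition expects;
#  * steadiness is (max - min) / |mean| < tol within the window, over a span
#    of at least 1 h.

#' Extraction configuration
#'
#' All thresholds of the daily-maximum extraction, with the study defaults.
#'
#' @param lat,lon site coordinates in degrees (defaults: the Tasmanian
#'   field site, 43.051 S, 147.104 E).
#' @param utc_offset UTC offset of the civil timestamps, hours.
#' @param night_vpd_max humid-night criterion: the whole midnight-sunrise
#'   interval must stay below this VPD (kPa) for a predawn anchor.
#' @param steady_tol steady-state tolerance: relative range of the 2-h
#'   window around the daytime minimum.
#' @param window_half_hours half-width of the averaging window (hours).
#' @param min_window_points minimum points in a valid window.
#' @param min_window_span_hours minimum time span of a valid window.
#' @param diurnal_window hours (start, end) for diurnal slicing.
#' @param max_anchor_gap_days interpolation spans longer than this are
#'   flagged with a warning.
#' @param min_night_points minimum climate points required to certify a
#'   night as humid.
#' @param season_fun function mapping a `Date` to a season label; the
#'   default is the calendar year, which matches single-summer growing
#'   seasons.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(lat = -43.051, lon = 147.104, utc_offset = 10,
                              night_vpd_max = 0.05, steady_tol = 0.05,
                              window_half_hours = 1, min_window_points = 4L,
                              min_window_span_hours = 1,
                              diurnal_window = c(11, 15),
                              max_anchor_gap_days = 21,
                              min_night_points = 4L,
                              season_fun = function(d) format(d, "%Y")) {
  structure(list(lat = lat, lon = lon, utc_offset = utc_offset,
                 night_vpd_max = night_vpd_max, steady_tol = steady_tol,
                 window_half_hours = window_half_hours,
                 min_window_points = as.integer(min_window_points),
                 min_window_span_hours = min_window_span_hours,
                 diurnal_window = diurnal_window,
                 max_anchor_gap_days = max_anchor_gap_days,
                 min_night_points = as.integer(min_night_points),
                 season_fun = season_fun),
            class = "extraction_config")
}

#' Locate the steady-state daytime minimum of one tree-day
#'
#' Finds the most negative daytime stem water potential, averages the
#' half-open 2-h window centred on it, and accepts the day only when the
#' window varies by less than the steady-state tolerance over at least 1 h.
#' Ties at the minimum resolve to the earliest time.
#'
#' @param day_psi data frame (`timestamp`, `psi_stem`) for a single plant
#'   and date.
#' @param daytime_window numeric (sunrise, sunset) in decimal hours.
#' @param config an [extraction_config].
#' @return `NULL` when no qualifying window exists; otherwise a list with
#'   `mean_psi` (MPa), `t_mid` (the minimum's timestamp), `window`
#'   (start/end POSIXct), and `n_points`.
#' @export
find_steady_state_min <- function(day_psi, daytime_window,
                                  config = extraction_config()) {
  h <- hour_of_day(day_psi$timestamp)
  day <- day_psi[h >= daytime_window[1] & h <= daytime_window[2], ]
  if (nrow(day) < config$min_window_points) return(NULL)
  half <- config$window_half_hours * 3600
  # ties at the minimum (e.g. a flat plateau): every tied point is a
  # candidate centre; keep the qualifying window with the most negative
  # mean (the plateau proper), earliest wins on equal means
  best <- NULL
  for (i_min in which(day$psi_stem == min(day$psi_stem))) {
    t_min <- day$timestamp[i_min]
    in_win <- day$timestamp >= t_min - half & day$timestamp < t_min + half
    w <- day[in_win, ]
    if (nrow(w) < config$min_window_points) next
    span <- diff(range(as.numeric(w$timestamp))) / 3600
    if (span < config$min_window_span_hours) next
    rng <- diff(range(w$psi_stem))
    m <- mean(w$psi_stem)
    steady <- rng == 0 || (abs(m) > 0 && rng / abs(m) < config$steady_tol)
    if (!steady) next
    if (is.null(best) || m < best$mean_psi) {
      best <- list(mean_psi = m, t_mid = t_min,
                   window = range(w$timestamp), n_points = nrow(w))
    }
  }
  best
}

#' Select predawn equilibrium anchors on humid nights
#'
#' A night (midnight to sunrise) qualifies when every climate record in it
#' stays below the humid-night VPD criterion (default 0.05 kPa, i.e.
#' humidity above ~95%), so nocturnal transpiration is negligible and
#' predawn stem water potential equilibrates with soil water potential.
#' The anchor value is the mean of the 2-h window containing the
#' pre-sunrise maximum of `psi_stem`.
#'
#' @param psi a `psi_series` (columns `plant_id`, `timestamp`, `psi_stem`).
#' @param climate a [climate_series].
#' @param config an [extraction_config].
#' @return data frame of anchors: `plant_id`, `date`, `timestamp` (time of
#'   the pre-sunrise maximum), `psi_predawn` (MPa), `night_max_vpd` (kPa),
#'   `n_points`. Errors when no night qualifies, since soil water
#'   potential cannot be tracked at all in that case.
#' @export
select_predawn_anchors <- function(psi, climate,
                                   config = extraction_config()) {
  cl_date <- date_of(climate$timestamp)
  cl_hour <- hour_of_day(climate$timestamp)
  psi_date <- date_of(psi$timestamp)
  psi_hour <- hour_of_day(psi$timestamp)
  dates <- sort(unique(psi_date))
  sun <- sunrise_sunset(dates, config$lat, config$lon, config$utc_offset)
  sunrise <- stats::setNames(sun$sunrise, as.character(sun$date))
  out <- list()
  for (p in unique(psi$plant_id)) {
    sel_p <- psi$plant_id == p
    for (d in as.character(dates)) {
      sr <- sunrise[[d]]
      night_cl <- climate$vpd[cl_date == as.Date(d) & cl_hour < sr]
      if (length(night_cl) < config$min_night_points) next
      if (any(is.na(night_cl)) || max(night_cl) >= config$night_vpd_max) next
      keep <- sel_p & psi_date == as.Date(d) & psi_hour < sr
      if (sum(keep) < config$min_window_points) next
      np <- psi[keep, ]
      i_max <- which.max(np$psi_stem)
      t_max <- np$timestamp[i_max]
      half <- config$window_half_hours * 3600
      w <- np[np$timestamp >= t_max - half & np$timestamp < t_max + half, ]
      out[[length(out) + 1L]] <- data.frame(
        plant_id = p, date = as.Date(d), timestamp = t_max,
        psi_predawn = mean(w$psi_stem), night_max_vpd = max(night_cl),
        n_points = nrow(w))
    }
  }
  if (length(out) == 0L) {
    stop("no qualifying humid nights (VPD < ", config$night_vpd_max,
         " kPa all night): soil water potential cannot be tracked")
  }
  anchors <- do.call(rbind, out)
  anchors[order(anchors$plant_id, anchors$date), ]
}

#' Interpolate soil water potential between predawn anchors
#'
#' Piecewise-linear interpolation of per-plant predawn anchors, exact at
#' anchor times. Queries outside the anchor span are refused (NA, with a
#' message); anchor gaps above the configured maximum are flagged.
#'
#' @param anchors anchors from [select_predawn_anchors] (one plant, or
#'   supply `plant_id` to select one).
#' @param times `POSIXct` query times.
#' @param plant_id plant to select when `anchors` holds several.
#' @param config an [extraction_config].
#' @return data frame of class `soil_track`: `plant_id`, `timestamp`,
#'   `psi_soil` (NA outside the anchor span).
#' @export
interpolate_soil_psi <- function(anchors, times, plant_id = NULL,
                                 config = extraction_config()) {
  if (!is.null(plant_id)) anchors <- anchors[anchors$plant_id == plant_id, ]
  p <- unique(anchors$plant_id)
  if (length(p) != 1L) {
    stop("anchors must be from a single plant (use plant_id=)")
  }
  if (nrow(anchors) < 2L) stop("need at least 2 anchors to interpolate")
  anchors <- anchors[order(anchors$timestamp), ]
  gaps <- diff(as.numeric(anchors$timestamp)) / 86400
  if (any(gaps > config$max_anchor_gap_days)) {
    warning(sum(gaps > config$max_anchor_gap_days), " anchor gap(s) > ",
            config$max_anchor_gap_days, " d for plant ", p,
            "; interpolation there is poorly constrained")
  }
  y <- stats::approx(as.numeric(anchors$timestamp), anchors$psi_predawn,
                     xout = as.numeric(times), rule = 1)$y
  n_out <- sum(is.na(y))
  if (n_out > 0) {
    message("interpolate_soil_psi: ", n_out,
            " query time(s) outside the anchor span dropped")
  }
  structure(data.frame(plant_id = p, timestamp = times, psi_soil = y),
            class = c("soil_track", "data.frame"))
}

#' Build steady-state daily maximum Delta-Psi records
#'
#' The unit of observation of the regulation model: for every tree-day,
#' the steady-state daytime minimum of stem water potential (2-h mean) is
#' subtracted from the interpolated daytime soil water potential
#' (evaluated at the window midpoint) to give `delta_psi_max`, paired with
#' the maximum daytime VPD of that day. Days without a steady state,
#' with negative `delta_psi_max`, or without soil coverage are excluded
#' with per-reason counts (attribute `exclusions`; the excluded rows are
#' in attribute `excluded`).
#'
#' @param psi a `psi_series` for one or more plants.
#' @param anchors predawn anchors from [select_predawn_anchors].
#' @param climate a [climate_series].
#' @param config an [extraction_config].
#' @return data frame with one row per retained tree-day: `plant_id`,
#'   `date`, `season`, `level` (plant-year), `delta_psi_max` (MPa),
#'   `vpd_max_day` (kPa), `vpd_window_mean` (kPa), `psi_soil_day` (MPa),
#'   `steady_state_flag`.
#' @export
build_daily_records <- function(psi, anchors, climate,
                                config = extraction_config()) {
  cl_date <- date_of(climate$timestamp)
  cl_hour <- hour_of_day(climate$timestamp)
  psi_date <- date_of(psi$timestamp)
  rows <- list(); excl <- list()
  for (p in unique(psi$plant_id)) {
    pp <- psi[psi$plant_id == p, ]
    pd <- psi_date[psi$plant_id == p]
    anc <- anchors[anchors$plant_id == p, ]
    dates <- sort(unique(pd))
    sun <- sunrise_sunset(dates, config$lat, config$lon, config$utc_offset)
    for (i in seq_along(dates)) {
      d <- dates[i]
      sr <- sun$sunrise[i]; ss <- sun$sunset[i]
      day_cl <- climate[cl_date == d & cl_hour >= sr & cl_hour <= ss, ]
      exclude <- function(reason) {
        excl[[length(excl) + 1L]] <<- data.frame(plant_id = p, date = d,
                                                 reason = reason)
      }
      if (nrow(day_cl) == 0L || all(is.na(day_cl$vpd))) {
        exclude("missing_climate"); next
      }
      steady <- find_steady_state_min(pp[pd == d, ], c(sr, ss), config)
      if (is.null(steady)) { exclude("no_steady_state"); next }
      if (nrow(anc) < 2L) { exclude("missing_soil"); next }
      soil <- stats::approx(as.numeric(anc$timestamp), anc$psi_predawn,
                            xout = as.numeric(steady$t_mid), rule = 1)$y
      if (is.na(soil)) { exclude("missing_soil"); next }
      delta <- soil - steady$mean_psi
      if (delta < 0) { exclude("negative_delta"); next }
      in_win <- day_cl$timestamp >= steady$window[1] &
        day_cl$timestamp <= steady$window[2]
      season <- config$season_fun(d)
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = p, date = d, season = season,
        level = paste(p, season, sep = ":"),
        delta_psi_max = delta,
        vpd_max_day = max(day_cl$vpd, na.rm = TRUE),
        vpd_window_mean = if (any(in_win)) mean(day_cl$vpd[in_win]) else NA,
        psi_soil_day = soil, steady_state_flag = TRUE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = character(), date = as.Date(character()),
               season = character(), level = character(),
               delta_psi_max = numeric(), vpd_max_day = numeric(),
               vpd_window_mean = numeric(), psi_soil_day = numeric(),
               steady_state_flag = logical())
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(plant_id = character(), date = as.Date(character()),
               reason = character())
  counts <- c(retained = nrow(records), table(excluded$reason))
  message("build_daily_records: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(records, excluded = excluded, exclusions = counts,
            class = c("daily_records", "data.frame"))
}

# nearest-neighbour index of each query time in a reference series,
# NA when farther than max_gap_min
nearest_time_index <- function(t_query, t_ref, max_gap_min = 10) {
  xq <- as.numeric(t_query); xr <- as.numeric(t_ref)
  lo <- findInterval(xq, xr)
  lo_i <- pmax(lo, 1L)
  hi_i <- pmin(lo + 1L, length(xr))
  pick <- ifelse(abs(xq - xr[lo_i]) <= abs(xq - xr[hi_i]), lo_i, hi_i)
  pick[abs(xq - xr[pick]) > max_gap_min * 60] <- NA_integer_
  pick
}

#' Time-aligned diurnal slice of Delta-Psi, VPD and soil water potential
#'
#' Pairs stem water potential with VPD (nearest climate record within 10
#' minutes) inside a fixed diurnal window (default 11:00-15:00), for
#' exploratory analysis of within-day regulation. No steady-state
#' requirement. When anchors are supplied, soil water potential and
#' `delta_psi` are attached.
#'
#' @param psi a `psi_series`.
#' @param climate a [climate_series].
#' @param anchors optional predawn anchors for soil interpolation.
#' @param window diurnal hours (start, end); overrides the config value.
#' @param config an [extraction_config].
#' @param max_gap_min maximum timestamp mismatch for the VPD join, minutes.
#' @return data frame: `plant_id`, `timestamp`, `psi_stem`, `vpd`, and
#'   (with anchors) `psi_soil`, `delta_psi`.
#' @export
diurnal_window_slice <- function(psi, climate, anchors = NULL,
                                 window = NULL,
                                 config = extraction_config(),
                                 max_gap_min = 10) {
  if (is.null(window)) window <- config$diurnal_window
  h <- hour_of_day(psi$timestamp)
  x <- psi[h >= window[1] & h <= window[2], , drop = FALSE]
  if (nrow(x) == 0L) {
    return(data.frame(plant_id = character(),
                      timestamp = as.POSIXct(character()),
                      psi_stem = numeric(), vpd = numeric()))
  }
  idx <- nearest_time_index(x$timestamp, climate$timestamp, max_gap_min)
  out <- data.frame(plant_id = x$plant_id, timestamp = x$timestamp,
                    psi_stem = x$psi_stem, vpd = climate$vpd[idx])
  out <- out[!is.na(out$vpd), ]
  if (!is.null(anchors)) {
    out$psi_soil <- NA_real_
    for (p in unique(out$plant_id)) {
      anc <- anchors[anchors$plant_id == p, ]
      if (nrow(anc) < 2L) next
      sel <- out$plant_id == p
      out$psi_soil[sel] <- stats::approx(as.numeric(anc$timestamp),
                                         anc$psi_predawn,
                                         xout = as.numeric(out$timestamp[sel]),
                                         rule = 1)$y
    }
    out$delta_psi <- out$psi_soil - out$psi_stem
  }
  rownames(out) <- NULL
  out
}

#' Write daily records (and exclusions) to CSV
#'
#' Long CSV with columns `plant_id,date,season,delta_psi_max_mpa,
#' vpd_max_kpa,psi_soil_mpa,excluded_reason`; retained rows have an empty
#' reason, excluded tree-days appear with NA measurements.
#'
#' @param records a `daily_records` object from [build_daily_records].
#' @param path output file.
#' @export
write_records_csv <- function(records, path) {
  kept <- data.frame(plant_id = records$plant_id,
                     date = as.character(records$date),
                     season = records$season,
                     delta_psi_max_mpa = records$delta_psi_max,
                     vpd_max_kpa = records$vpd_max_day,
                     psi_soil_mpa = records$psi_soil_day,
                     excluded_reason = "")
  ex <- attr(records, "excluded")
  if (!is.null(ex) && nrow(ex)) {
    kept <- rbind(kept, data.frame(plant_id = ex$plant_id,
                                   date = as.character(ex$date),
                                   season = NA, delta_psi_max_mpa = NA,
                                   vpd_max_kpa = NA, psi_soil_mpa = NA,
                                   excluded_reason = ex$reason))
  }
  utils::write.csv(kept[order(kept$plant_id, kept$date), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily records written by [write_records_csv]
#'
#' Excluded rows are dropped; `level` is rebuilt as plant:season.
#'
#' @param path CSV path.
#' @return a data frame suitable for [fit_posterior].
#' @export
read_records_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(season = "character"))
  x <- x[is.na(x$excluded_reason) | x$excluded_reason == "", ]
  data.frame(plant_id = x$plant_id, date = as.Date(x$date),
             season = x$season,
             level = paste(x$plant_id, x$season, sep = ":"),
             delta_psi_max = x$delta_psi_max_mpa,
             vpd_max_day = x$vpd_max_kpa,
             psi_soil_day = x$psi_soil_mpa)
}
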