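#' Saturation vapour pressure over water (Buck 1981)
#'
#' \eqn{e_s(T) = 0.61121 \exp\left[(18.678 - T/234.5)\,
#'   T/(257.14 + T)\right]} kPa, the revised Buck formula for saturation
#' vapour pressure over liquid water; strictly increasing on (-20, 60) degC.
#'
#' @param air_temp air temperature in degrees Celsius (vectorized).
#' @return saturation vapour pressure in kPa.
#' @export
buck_svp <- function(air_temp) {
  0.61121 * exp((18.678 - air_temp / 234.5) * (air_temp / (257.14 + air_temp)))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' \eqn{VPD = e_s(T)(1 - RH/100)} with [buck_svp] saturation pressure.
#' Exactly zero at saturation (`rh = 100`). Supersaturated readings
#' (`rh > 100`, sensor artefacts) are clamped to 100 with a warning so that
#' humid nights are preserved rather than dropped; `rh < 0` or temperatures
#' outside (-20, 60) degC are rejected (NA with a warning).
#'
#' @param air_temp air temperature, degC (vectorized).
#' @param rh relative humidity in percent, `[0, 100]`.
#' @return VPD in kPa (>= 0), NA for rejected records.
#' @examples
#' compute_vpd(20, 100)  # 0
#' compute_vpd(20, 50)   # ~1.169
#' @export
compute_vpd <- function(air_temp, rh) {
  n <- max(length(air_temp), length(rh))
  air_temp <- rep_len(air_temp, n)
  rh <- rep_len(rh, n)
  bad_t <- !is.na(air_temp) & (air_temp <= -20 | air_temp >= 60)
  bad_rh <- !is.na(rh) & rh < 0
  if (any(bad_t)) {
    warning(sum(bad_t), " record(s) rejected: air_temp outside (-20, 60) degC")
  }
  if (any(bad_rh)) {
    warning(sum(bad_rh), " record(s) rejected: rh < 0%")
  }
  super <- !is.na(rh) & rh > 100
  if (any(super)) {
    warning(sum(super), " supersaturated record(s) (rh > 100%) clamped to 100%")
    rh[super] <- 100
  }
  vpd <- buck_svp(air_temp) * (1 - rh / 100)
  vpd[bad_t | bad_rh] <- NA_real_
  vpd
}

#' Assemble a climate series with computed VPD
#'
#' Builds the site-level microclimate table used throughout the pipeline:
#' strictly increasing timestamps at a 15-30 min cadence (longer intervals
#' are permitted but flagged as gaps), air temperature, relative humidity,
#' and VPD computed with [compute_vpd]. Records rejected by the VPD rules
#' are dropped with a message.
#'
#' @param timestamp `POSIXct` timestamps in site-local civil time.
#' @param air_temp air temperature, degC.
#' @param rh relative humidity, percent.
#' @return data frame of class `climate_series` with columns `timestamp`,
#'   `air_temp`, `rh`, `vpd`; the number of cadence gaps (> 30 min) is
#'   attached as attribute `n_gaps`.
#' @export
climate_series <- function(timestamp, air_temp, rh) {
  stopifnot(inherits(timestamp, "POSIXct"))
  if (is.unsorted(as.numeric(timestamp), strictly = TRUE)) {
    stop("climate timestamps must be strictly increasing")
  }
  vpd <- compute_vpd(air_temp, rh)
  rh <- pmin(rh, 100)
  drop <- is.na(vpd)
  if (any(drop)) {
    message("climate_series: dropped ", sum(drop), " rejected record(s)")
  }
  x <- data.frame(timestamp = timestamp, air_temp = air_temp,
                  rh = rh, vpd = vpd)[!drop, ]
  dt <- diff(as.numeric(x$timestamp)) / 60
  n_gaps <- sum(dt > 30 + 1e-9)
  if (n_gaps > 0) {
    message("climate_series: ", n_gaps, " cadence gap(s) > 30 min flagged")
  }
  structure(x, n_gaps = n_gaps, class = c("climate_series", "data.frame"))
}

#' Read a climate CSV (`timestamp,temp_c,rh_pct`)
#'
#' @param path CSV file with ISO-8601 timestamps in site-local time.
#' @return a [climate_series].
#' @export
read_climate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c", "rh_pct")
  if (!all(need %in% names(x))) {
    stop("climate CSV must have columns: ", paste(need, collapse = ","))
  }
  climate_series(parse_timestamp(x$timestamp), x$temp_c, x$rh_pct)
}

#' Write a climate series as tidy CSV (`timestamp,vpd_kpa`)
#'
#' @param climate a [climate_series].
#' @param path output file.
#' @export
write_vpd_csv <- function(climate, path) {
  utils::write.csv(
    data.frame(timestamp = format(climate$timestamp, "%Y-%m-%dT%H:%M:%S"),
               vpd_kpa = climate$vpd),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
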