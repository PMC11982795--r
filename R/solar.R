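# Sunrise/sunset from solar geometry (NOAA solar-calculator equations).
# Timestamps in this package are site-local civil time; the UTC offset of
# that civil time is a configuration value (no DST arithmetic).

#' Sunrise and sunset times for a date and site
#'
#' NOAA low-precision solar equations: fractional-year phase, equation of
#' time, solar declination, and the hour angle at a zenith of 90.833 degrees
#' (official sunrise, including refraction). Accurate to a couple of
#' minutes, ample for windowing dendrometer series.
#'
#' @param date a `Date` (vectorized).
#' @param lat,lon site latitude/longitude, degrees (south/west negative).
#' @param utc_offset offset of local civil time from UTC, hours.
#' @return data frame with `date`, `sunrise` and `sunset` in decimal hours
#'   of local civil time.
#' @export
sunrise_sunset <- function(date, lat = -43.051, lon = 147.104,
                           utc_offset = 10) {
  doy <- as.integer(format(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) -
    tan(phi) * tan(decl)
  cos_ha <- pmin(1, pmax(-1, cos_ha))  # polar day/night degenerate to 0/24 h
  ha <- acos(cos_ha) * 180 / pi
  sunrise <- (720 - 4 * (lon + ha) - eqtime + utc_offset * 60) %% 1440 / 60
  sunset <- (720 - 4 * (lon - ha) - eqtime + utc_offset * 60) %% 1440 / 60
  data.frame(date = date, sunrise = sunrise, sunset = sunset)
}

#' Decimal hour of day of a timestamp (in its stored clock time)
#' @param t `POSIXct`.
#' @return numeric hours in `[0, 24)`.
#' @export
hour_of_day <- function(t) {
  as.numeric(format(t, "%H")) + as.numeric(format(t, "%M")) / 60 +
    as.numeric(format(t, "%S")) / 3600
}

#' Calendar date of a timestamp (in its stored clock time)
#' @param t `POSIXct`.
#' @return `Date`.
#' @export
date_of <- function(t) as.Date(format(t, "%Y-%m-%d"))

# ISO-8601 parser ('T' or space separated), site-local civil time kept as UTC
parse_timestamp <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"))
}
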