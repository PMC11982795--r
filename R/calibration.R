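#' Fit a per-plant width-to-water-potential calibration line
#'
#' Ordinary least-squares line \eqn{\Psi_{stem} = a \cdot width + b} relating
#' branchlet width (optical dendrometer signal, micrometres) to
#' pressure-chamber stem water potential (MPa). One line per plant, fitted
#' once over all paired points.
#'
#' @param obs data frame of calibration observations for a single plant,
#'   with columns `plant_id`, `psi_bomb` (MPa, <= 0) and `width_at_time`
#'   (micrometres); a `timestamp` column is carried if present.
#' @return list of class `calibration_model`: `plant_id`, `slope`
#'   (MPa per micrometre), `intercept` (MPa), `r_squared`, `n_points`.
#' @export
fit_width_calibration <- function(obs) {
  if (nrow(obs) < 2L) stop("calibration needs at least 2 paired points")
  if (length(unique(obs$plant_id)) != 1L) {
    stop("calibration observations must come from a single plant")
  }
  if (any(obs$psi_bomb > 0)) stop("psi_bomb must be <= 0 MPa")
  w <- obs$width_at_time
  if (diff(range(w)) <= 0) {
    stop("calibration failure: width range is degenerate (constant width)")
  }
  fit <- stats::lm(psi_bomb ~ width_at_time, data = obs)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((obs$psi_bomb - mean(obs$psi_bomb))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(plant_id = as.character(obs$plant_id[1]),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 n_points = nrow(obs)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration %s: Psi = %.5g * width %+.4g  (r2 = %.3f, n = %d)\n",
    x$plant_id, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert a branchlet-width series to stem water potential
#'
#' Applies a fitted calibration line to a width series. Values implying
#' \eqn{\Psi_{stem} > 0} (sensor drift) are clipped to 0 and flagged.
#'
#' @param widths data frame with columns `timestamp`, `plant_id`,
#'   `width` (micrometres), strictly increasing timestamps per plant.
#' @param model a [fit_width_calibration] result for the same plant.
#' @return data frame of class `psi_series` with columns `plant_id`,
#'   `timestamp`, `psi_stem` (MPa, <= 0) and `flagged` (drift-clipped).
#' @export
apply_calibration <- function(widths, model) {
  if (nrow(widths) == 0L) {
    return(structure(data.frame(plant_id = character(),
                                timestamp = as.POSIXct(character()),
                                psi_stem = numeric(), flagged = logical()),
                     class = c("psi_series", "data.frame")))
  }
  if (!all(as.character(widths$plant_id) == model$plant_id)) {
    stop("calibration model is for plant ", model$plant_id,
         " but the series contains other plants")
  }
  psi <- model$slope * widths$width + model$intercept
  flagged <- psi >= 0  # at or above the saturation boundary is suspicious
  if (any(psi > 0)) {
    message("apply_calibration: ", sum(psi > 0),
            " value(s) > 0 MPa clipped to 0 (sensor drift)")
    psi[psi > 0] <- 0
  }
  structure(data.frame(plant_id = as.character(widths$plant_id),
                       timestamp = widths$timestamp,
                       psi_stem = psi, flagged = flagged),
            class = c("psi_series", "data.frame"))
}

#' Read a width CSV (`timestamp,plant_id,width_um`)
#'
#' @param path CSV file with ISO-8601 timestamps.
#' @return data frame with `timestamp`, `plant_id`, `width`, sorted by
#'   plant then time.
#' @export
read_width_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "plant_id", "width_um")
  if (!all(need %in% names(x))) {
    stop("width CSV must have columns: ", paste(need, collapse = ","))
  }
  out <- data.frame(timestamp = parse_timestamp(x$timestamp),
                    plant_id = as.character(x$plant_id),
                    width = x$width_um)
  out <- out[order(out$plant_id, out$timestamp), ]
  for (p in unique(out$plant_id)) {
    tt <- out$timestamp[out$plant_id == p]
    if (is.unsorted(as.numeric(tt), strictly = TRUE)) {
      stop("width timestamps must be strictly increasing within plant ", p)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a stem water potential series as tidy CSV
#'
#' Columns `timestamp,plant_id,psi_stem_mpa`.
#'
#' @param psi a `psi_series` (or equivalently shaped data frame).
#' @param path output file.
#' @export
write_psi_csv <- function(psi, path) {
  utils::write.csv(
    data.frame(timestamp = format(psi$timestamp, "%Y-%m-%dT%H:%M:%S"),
               plant_id = psi$plant_id, psi_stem_mpa = psi$psi_stem),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
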