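# Whole-plant diffusive conductance inferred from the Delta-Psi surface.
#
# Under Darcy's law with constant soil-to-leaf hydraulic conductance K_s-p,
# transpiration E = K_s-p * Delta-Psi, and under Fick's law E = g_c * VPD,
# so g_c is proportional to K_s-p * Delta-Psi / VPD. The constant cancels
# under normalization to the surface maximum, so only relative conductance
# (percent of maximum) is reported.

#' Relative whole-plant diffusive conductance (unnormalized)
#'
#' \eqn{g_c \propto \theta(\Psi_{soil})(1 - e^{-\lambda(\Psi_{soil})VPD})
#' / VPD}, with the VPD -> 0 limit handled analytically as
#' \eqn{\theta(\Psi_{soil})\lambda(\Psi_{soil})} (the surface maximum at
#' hydrated soil). Proportionality constant (hydraulic conductance)
#' omitted; it cancels under normalization.
#'
#' @param vpd vapour pressure deficit, kPa (>= 0; vectorized).
#' @param psi_soil soil water potential, MPa.
#' @param p a [population_params] object.
#' @return unnormalized relative conductance.
#' @export
gc_relative <- function(vpd, psi_soil, p) {
  if (any(vpd < 0)) stop("vpd must be >= 0")
  th <- theta_at(psi_soil, p)
  lam <- lambda_at(psi_soil, p)
  n <- max(length(vpd), length(th))
  vpd <- rep_len(vpd, n); th <- rep_len(th, n); lam <- rep_len(lam, n)
  out <- ifelse(vpd == 0, th * lam, th * (1 - exp(-lam * vpd)) / vpd)
  out
}

#' Percentage decline in conductance from the low-VPD limit
#'
#' \eqn{100 (1 - g_c(VPD_{hi}) / g_c(0^+))} at fixed soil water potential:
#' how much stomata are inferred to close as VPD rises from ~0 to
#' `vpd_hi`. Strictly increasing in `vpd_hi` since \eqn{(1-e^{-x})/x} is
#' strictly decreasing.
#'
#' @param vpd_hi upper VPD, kPa (> 0).
#' @param psi_soil soil water potential, MPa.
#' @param p a [population_params] object.
#' @return decline in percent.
#' @examples
#' p <- population_params(theta0 = 1, lambda0 = -log(0.05) / 1.94)
#' fractional_decline(4, 0, p)  # ~83.8
#' @export
fractional_decline <- function(vpd_hi, psi_soil, p) {
  100 * (1 - gc_relative(vpd_hi, psi_soil, p) / gc_relative(0, psi_soil, p))
}

#' Normalized conductance surface over a VPD x soil water potential grid
#'
#' Evaluates [gc_relative] over the grid and normalizes to the grid
#' maximum, expressed as a percentage (the maximum sits at the smallest
#' VPD and any soil water potential at or above the threshold).
#'
#' @param p a [population_params] object.
#' @param vpd_grid VPD values, kPa (> 0, or 0 for the analytic limit).
#' @param psi_grid soil water potential values, MPa (<= 0).
#' @return object of class `gc_surface`: list with `vpd`, `psi_soil`, and
#'   `gc_pct` (matrix, rows = VPD, columns = soil water potential, max =
#'   100). `as.data.frame()` yields long format `vpd_kpa, psi_soil_mpa,
#'   gc_pct`.
#' @export
gc_surface <- function(p, vpd_grid = seq(0.05, 4, by = 0.05),
                       psi_grid = seq(0, -4, by = -0.05)) {
  if (length(vpd_grid) == 0L || length(psi_grid) == 0L) {
    stop("grids must be nonempty")
  }
  m <- outer(vpd_grid, psi_grid, function(v, ps) gc_relative(v, ps, p))
  m <- 100 * m / max(m)
  structure(list(vpd = vpd_grid, psi_soil = psi_grid, gc_pct = m,
                 params = p),
            class = "gc_surface")
}

#' @export
as.data.frame.gc_surface <- function(x, ...) {
  data.frame(vpd_kpa = rep(x$vpd, times = length(x$psi_soil)),
             psi_soil_mpa = rep(x$psi_soil, each = length(x$vpd)),
             gc_pct = as.vector(x$gc_pct))
}

#' @export
print.gc_surface <- function(x, ...) {
  cat(sprintf("g_c surface: %d VPD x %d Psi_soil cells (max 100%%)\n",
              length(x$vpd), length(x$psi_soil)))
  cat(sprintf("  VPD %g..%g kPa; Psi_soil %g..%g MPa; min %.1f%%\n",
              min(x$vpd), max(x$vpd), max(x$psi_soil), min(x$psi_soil),
              min(x$gc_pct)))
  invisible(x)
}

#' Write a conductance surface as long-format CSV
#'
#' Columns `vpd_kpa,psi_soil_mpa,gc_pct`.
#'
#' @param surface a [gc_surface] result.
#' @param path output file.
#' @export
write_gc_csv <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
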