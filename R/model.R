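#' Population-level parameters of the water-potential regulation model
#'
#' Bundles the six population-level parameters of the saturating
#' soil-to-stem water potential difference model
#' \deqn{\Delta\Psi = \theta(\Psi_{soil}) \left(1 - e^{-\lambda(\Psi_{soil})
#'   \cdot VPD}\right) + \varepsilon, \quad \varepsilon \sim N(0, \sigma^2)}
#' where the asymptote \eqn{\theta} and curvature rate \eqn{\lambda} are
#' constant (\eqn{\theta_0}, \eqn{\lambda_0}) while soil water potential sits
#' above a changepoint, and change exponentially below it:
#' \eqn{\theta = \theta_0 e^{-\alpha(\Psi_{thr} - \Psi_{soil})}} and
#' \eqn{\lambda = \lambda_0 e^{-\beta(\Psi_{thr} - \Psi_{soil})}} for
#' \eqn{\Psi_{soil} < \Psi_{thr}}.
#'
#' @param theta0 asymptote of \eqn{\Delta\Psi} at hydrated soil (MPa, > 0).
#' @param lambda0 curvature rate at hydrated soil (kPa^-1, > 0).
#' @param alpha decay rate of the asymptote below the threshold (MPa^-1);
#'   positive values shrink the asymptote as soil dries.
#' @param beta decay rate of the curvature below the threshold (MPa^-1);
#'   negative values make \eqn{\lambda} increase as soil dries.
#' @param psi_threshold soil water potential changepoint (MPa, <= 0).
#' @param sigma residual standard deviation (MPa, > 0).
#' @return An object of class `population_params` (a named list).
#' @examples
#' p <- population_params(theta0 = 1.2, lambda0 = 1.5, alpha = 0.29,
#'                        beta = -0.22, psi_threshold = -0.83, sigma = 0.08)
#' theta_at(-4, p)
#' @export
population_params <- function(theta0, lambda0, alpha = 0, beta = 0,
                              psi_threshold = 0, sigma = 0.1) {
  stopifnot(is.numeric(theta0), length(theta0) == 1L, theta0 > 0,
            is.numeric(lambda0), length(lambda0) == 1L, lambda0 > 0,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(psi_threshold), length(psi_threshold) == 1L,
            psi_threshold <= 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  structure(list(theta0 = theta0, lambda0 = lambda0, alpha = alpha,
                 beta = beta, psi_threshold = psi_threshold, sigma = sigma),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters (Delta-Psi regulation model)\n")
  cat(sprintf("  theta0        %8.4f MPa   (asymptote, hydrated soil)\n", x$theta0))
  cat(sprintf("  lambda0       %8.4f kPa^-1 (curvature, hydrated soil)\n", x$lambda0))
  cat(sprintf("  alpha         %8.4f MPa^-1 (asymptote decay below threshold)\n", x$alpha))
  cat(sprintf("  beta          %8.4f MPa^-1 (curvature decay below threshold)\n", x$beta))
  cat(sprintf("  psi_threshold %8.4f MPa   (soil changepoint)\n", x$psi_threshold))
  cat(sprintf("  sigma         %8.4f MPa   (residual SD)\n", x$sigma))
  invisible(x)
}

#' Asymptote of the Delta-Psi response at a given soil water potential
#'
#' Evaluates \eqn{\theta(\Psi_{soil})}: equal to `theta0` at or above the
#' changepoint, decaying exponentially at rate `alpha` below it. Continuous
#' at the changepoint by construction.
#'
#' @param psi_soil soil water potential (MPa, vectorized).
#' @param p a [population_params] object.
#' @return \eqn{\theta} in MPa, same length as `psi_soil`.
#' @export
theta_at <- function(psi_soil, p) {
  d <- pmax(0, p$psi_threshold - psi_soil)
  p$theta0 * exp(-p$alpha * d)
}

#' Curvature rate of the Delta-Psi response at a given soil water potential
#'
#' Evaluates \eqn{\lambda(\Psi_{soil})}: equal to `lambda0` at or above the
#' changepoint, changing exponentially at rate `beta` below it (a negative
#' `beta` makes \eqn{\lambda} increase as soil dries).
#'
#' @inheritParams theta_at
#' @return \eqn{\lambda} in kPa^-1, same length as `psi_soil`.
#' @export
lambda_at <- function(psi_soil, p) {
  d <- pmax(0, p$psi_threshold - psi_soil)
  p$lambda0 * exp(-p$beta * d)
}

#' Expected steady-state daily maximum Delta-Psi
#'
#' The mean part of the observation model:
#' \eqn{\theta(\Psi_{soil})(1 - e^{-\lambda(\Psi_{soil}) VPD})}.
#' Strictly increasing in VPD and bounded above by \eqn{\theta(\Psi_{soil})}.
#'
#' @param vpd vapour pressure deficit (kPa, >= 0, vectorized).
#' @param psi_soil soil water potential (MPa, vectorized or scalar).
#' @param p a [population_params] object.
#' @return expected \eqn{\Delta\Psi} in MPa.
#' @export
mean_delta_psi <- function(vpd, psi_soil, p) {
  if (any(vpd < 0)) stop("vpd must be >= 0")
  theta_at(psi_soil, p) * (1 - exp(-lambda_at(psi_soil, p) * vpd))
}

#' VPD at which Delta-Psi reaches a given fraction of its asymptote
#'
#' Inverts the saturating curve: the VPD where
#' \eqn{1 - e^{-\lambda VPD} = f}, i.e. \eqn{-\log(1-f)/\lambda}.
#'
#' @param f target fraction of the asymptote, in (0, 1).
#' @param lam curvature rate \eqn{\lambda} (kPa^-1, > 0).
#' @return VPD in kPa.
#' @examples
#' vpd_at_fraction(0.95, 1.5442)  # ~1.94 kPa
#' @export
vpd_at_fraction <- function(f, lam) {
  if (any(f <= 0) || any(f >= 1)) stop("f must be in (0, 1)")
  if (any(lam <= 0)) stop("lam must be > 0")
  -log(1 - f) / lam
}

#' Correlated plant-year random effects on the log scale
#'
#' Describes multiplicative plant-year variation in `theta0` and `lambda0`:
#' each level (plant-year combination) carries a pair of log-scale offsets
#' drawn from a bivariate normal with the given standard deviations and
#' correlation, so level-specific parameters are
#' \eqn{\theta_{0,l} = \theta_0 e^{u_{1l}}},
#' \eqn{\lambda_{0,l} = \lambda_0 e^{u_{2l}}}, preserving positivity.
#'
#' @param levels character vector of plant-year level identifiers.
#' @param offsets numeric matrix with one row per level and two columns
#'   (log-theta0 and log-lambda0 offsets); defaults to zeros.
#' @param sd_log_theta0,sd_log_lambda0 random-effect SDs on the log scale.
#' @param correlation correlation of the two offsets, in (-1, 1).
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(levels, offsets = NULL,
                           sd_log_theta0 = 0, sd_log_lambda0 = 0,
                           correlation = 0) {
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("duplicate level identifiers")
  if (is.null(offsets)) {
    offsets <- matrix(0, nrow = length(levels), ncol = 2)
  }
  offsets <- as.matrix(offsets)
  stopifnot(nrow(offsets) == length(levels), ncol(offsets) == 2,
            sd_log_theta0 >= 0, sd_log_lambda0 >= 0,
            correlation > -1, correlation < 1)
  rownames(offsets) <- levels
  colnames(offsets) <- c("log_theta0", "log_lambda0")
  structure(list(levels = levels, offsets = offsets,
                 sd_log_theta0 = sd_log_theta0,
                 sd_log_lambda0 = sd_log_lambda0,
                 correlation = correlation),
            class = "random_effects")
}

#' Log-likelihood of daily maximum Delta-Psi records
#'
#' Gaussian log-likelihood of observed records under the changepoint model
#' with level-specific `theta0` and `lambda0` given by multiplicative
#' random-effect offsets. Each record must carry a `level` (plant-year
#' identifier) present in `re`.
#'
#' @param records data frame with columns `delta_psi_max`, `vpd_max_day`,
#'   `psi_soil_day` and `level` (see [build_daily_records]).
#' @param p a [population_params] object.
#' @param re a [random_effects] object; defaults to no random variation
#'   (all offsets zero, single implicit level).
#' @return the summed log-likelihood (scalar).
#' @export
log_likelihood <- function(records, p, re = NULL) {
  if (nrow(records) == 0L) return(0)
  if (is.null(re)) {
    off1 <- off2 <- numeric(nrow(records))
  } else {
    idx <- match(as.character(records$level), re$levels)
    if (anyNA(idx)) {
      stop("records contain levels absent from the random-effects spec: ",
           paste(unique(records$level[is.na(idx)]), collapse = ", "))
    }
    off1 <- re$offsets[idx, 1L]
    off2 <- re$offsets[idx, 2L]
  }
  d <- pmax(0, p$psi_threshold - records$psi_soil_day)
  theta <- p$theta0 * exp(off1 - p$alpha * d)
  lam <- p$lambda0 * exp(off2 - p$beta * d)
  mu <- theta * (1 - exp(-lam * records$vpd_max_day))
  sum(stats::dnorm(records$delta_psi_max, mean = mu, sd = p$sigma, log = TRUE))
}

#' Serialize population parameters to JSON with unit-annotated keys
#'
#' @param p a [population_params] object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
params_to_json <- function(p, path = NULL) {
  x <- list(theta0_mpa = p$theta0, lambda0_per_kpa = p$lambda0,
            alpha_per_mpa = p$alpha, beta_per_mpa = p$beta,
            psi_threshold_mpa = p$psi_threshold, sigma_mpa = p$sigma)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read population parameters from JSON written by [params_to_json]
#'
#' @param path file path or a JSON string.
#' @return a [population_params] object.
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  population_params(theta0 = x$theta0_mpa, lambda0 = x$lambda0_per_kpa,
                    alpha = x$alpha_per_mpa, beta = x$beta_per_mpa,
                    psi_threshold = x$psi_threshold_mpa, sigma = x$sigma_mpa)
}
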