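# Hierarchical Bayesian fit of the Delta-Psi changepoint model.
#
# Parameterization (unconstrained sampling space):
#   log theta0, log lambda0, log alpha, beta, log(-psi_threshold), log sigma,
#   log sd_log_theta0, log sd_log_lambda0, atanh(correlation),
#   and non-centred standard-normal offsets z1, z2 (one pair per plant-year
#   level). Positivity constraints are enforced by the log transforms; all
#   Jacobian terms are included in the target density.

#' Configuration for the Bayesian fit
#'
#' @param n_chains number of MCMC chains (>= 2 needed for R-hat).
#' @param n_iterations iterations per chain, warmup included.
#' @param warmup_frac fraction of each chain discarded as warmup.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param n_leapfrog base number of leapfrog steps (jittered 0.5x-1.5x).
#' @param target_accept dual-averaging target acceptance probability.
#' @param threshold logical; `FALSE` fits the no-changepoint limiting case
#'   (`alpha = beta = 0`, no threshold parameter).
#' @param parameterization `"centered"` (default) samples the level-specific
#'   log parameters directly with a bivariate-normal hierarchy prior --
#'   the efficient choice when each plant-year level carries many records,
#'   as in this design. `"noncentered"` samples standardized offsets,
#'   preferable only when levels are data-poor.
#' @param rhat_limit convergence gate; fits with any R-hat above it are
#'   flagged as non-converged.
#' @param prior named list of prior hyperparameters. Defaults (weakly
#'   informative, documented in the methods vignette):
#'   `lt0`, `ll0`: normal (mean, sd) on log theta0 / log lambda0, both
#'   N(0, 1); `alpha_sd`: half-normal SD for alpha (0.5); `beta_sd`: normal
#'   SD for beta (0.5, sign-free); `thr`: normal (mean, sd) on the
#'   threshold, N(-1, 1) truncated at 0; `sigma_sd`, `re_sd`: half-normal
#'   SDs for the residual and random-effect scales (0.5); correlation
#'   uniform on (-1, 1).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4L, n_iterations = 2000L,
                       warmup_frac = 0.5, seed = 1L, n_leapfrog = 24L,
                       target_accept = 0.85, threshold = TRUE,
                       rhat_limit = 1.01, prior = list(),
                       parameterization = c("centered", "noncentered")) {
  stopifnot(n_chains >= 1L, n_iterations >= 20L,
            warmup_frac > 0, warmup_frac < 1)
  parameterization <- match.arg(parameterization)
  default_prior <- list(lt0 = c(0, 1), ll0 = c(0, 1), alpha_sd = 0.5,
                        beta_sd = 0.5, thr = c(-1, 1), sigma_sd = 0.5,
                        re_sd = 0.5)
  prior <- utils::modifyList(default_prior, prior)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 warmup_frac = warmup_frac, seed = as.integer(seed),
                 n_leapfrog = as.integer(n_leapfrog),
                 target_accept = target_accept, threshold = isTRUE(threshold),
                 rhat_limit = rhat_limit, prior = prior,
                 parameterization = parameterization),
            class = "fit_config")
}

model_data <- function(records) {
  need <- c("delta_psi_max", "vpd_max_day", "psi_soil_day", "level")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  level <- as.character(records$level)
  levs <- sort(unique(level))
  list(y = as.numeric(records$delta_psi_max),
       V = as.numeric(records$vpd_max_day),
       P = as.numeric(records$psi_soil_day),
       lev = match(level, levs), levels = levs,
       L = length(levs), n = nrow(records))
}

param_map <- function(L, threshold, hierarchical) {
  i <- 0L
  nxt <- function(k = 1L) { out <- i + seq_len(k); i <<- i + k; out }
  map <- list(lt0 = nxt(), ll0 = nxt())
  if (threshold) {
    map$a_raw <- nxt(); map$beta <- nxt(); map$t_raw <- nxt()
  }
  map$lsig <- nxt()
  if (hierarchical) {
    map$ls1 <- nxt(); map$ls2 <- nxt(); map$rr <- nxt()
    map$z1 <- nxt(L); map$z2 <- nxt(L)
  }
  map$dim <- i
  map
}

# log posterior and gradient on the unconstrained scale.
# In the centered parameterization the z1/z2 slots hold the level-specific
# log theta0 / log lambda0 directly; in the non-centered one they hold
# standardized offsets.
make_lp_grad <- function(dat, map, prior, threshold, hierarchical,
                         centered = TRUE) {
  n <- dat$n; y <- dat$y; V <- dat$V; P <- dat$P
  lev <- dat$lev; L <- dat$L
  # dense indicator for fast per-level gradient sums via BLAS
  ind_lev <- matrix(0, n, L)
  ind_lev[cbind(seq_len(n), lev)] <- 1
  function(q) {
    grad <- numeric(map$dim)
    lt0 <- q[map$lt0]; ll0 <- q[map$ll0]; lsig <- q[map$lsig]
    sig <- exp(lsig)
    if (threshold) {
      a_raw <- q[map$a_raw]; be <- q[map$beta]; t_raw <- q[map$t_raw]
      al <- exp(a_raw); thr <- -exp(t_raw)
    }
    if (hierarchical) {
      ls1 <- q[map$ls1]; ls2 <- q[map$ls2]; rr <- q[map$rr]
      s1 <- exp(ls1); s2 <- exp(ls2)
      rho <- tanh(rr); qr <- sqrt(1 - rho^2)
      z1 <- q[map$z1]; z2 <- q[map$z2]
      if (centered) {
        u1 <- z1 - lt0; u2 <- z2 - ll0  # z holds level log-params
      } else {
        u1 <- s1 * z1; u2 <- s2 * (rho * z1 + qr * z2)
      }
      o1 <- u1[lev]; o2 <- u2[lev]
    } else {
      o1 <- o2 <- 0
    }
    if (threshold) {
      d <- pmax(0, thr - P)
      lth <- lt0 + o1 - al * d
      lla <- ll0 + o2 - be * d
    } else {
      d <- 0
      lth <- lt0 + o1
      lla <- ll0 + o2
    }
    if (any(lth > 25) || any(lla > 25) || lsig > 25) {
      return(list(lp = -Inf, grad = grad))
    }
    th <- exp(lth); lam <- exp(lla)
    E <- exp(-lam * V)
    mu <- th * (1 - E)
    res <- y - mu
    lp <- -n * lsig - 0.5 * n * log(2 * pi) - 0.5 * sum(res^2) / sig^2
    r <- res / sig^2
    Gth <- r * mu
    Gla <- r * th * V * E * lam
    lp <- lp - (lt0 - prior$lt0[1])^2 / (2 * prior$lt0[2]^2)
    lp <- lp - (ll0 - prior$ll0[1])^2 / (2 * prior$ll0[2]^2)
    data_g_lt0 <- if (hierarchical && centered) 0 else sum(Gth)
    data_g_ll0 <- if (hierarchical && centered) 0 else sum(Gla)
    grad[map$lt0] <- data_g_lt0 - (lt0 - prior$lt0[1]) / prior$lt0[2]^2
    grad[map$ll0] <- data_g_ll0 - (ll0 - prior$ll0[1]) / prior$ll0[2]^2
    if (threshold) {
      ind <- as.numeric(d > 0)
      lp <- lp - al^2 / (2 * prior$alpha_sd^2) + a_raw
      grad[map$a_raw] <- (-sum(Gth * d) - al / prior$alpha_sd^2) * al + 1
      lp <- lp - be^2 / (2 * prior$beta_sd^2)
      grad[map$beta] <- -sum(Gla * d) - be / prior$beta_sd^2
      g_thr <- -al * sum(Gth * ind) - be * sum(Gla * ind) -
        (thr - prior$thr[1]) / prior$thr[2]^2
      lp <- lp - (thr - prior$thr[1])^2 / (2 * prior$thr[2]^2) + t_raw
      grad[map$t_raw] <- g_thr * thr + 1
    }
    lp <- lp - sig^2 / (2 * prior$sigma_sd^2) + lsig
    grad[map$lsig] <- (sum(res^2) / sig^2 - n) - sig^2 / prior$sigma_sd^2 + 1
    if (hierarchical) {
      AB <- crossprod(ind_lev, cbind(Gth, Gla))
      A <- AB[, 1L]; B <- AB[, 2L]
      sre <- prior$re_sd
      # half-normal priors on the RE scales (+ log Jacobians), uniform on rho
      lp <- lp - s1^2 / (2 * sre^2) + ls1 - s2^2 / (2 * sre^2) + ls2 +
        log1p(-rho^2)
      if (centered) {
        cc <- 1 / (1 - rho^2)
        e1 <- u1 / s1; e2 <- u2 / s2
        Q <- e1^2 - 2 * rho * e1 * e2 + e2^2
        lp <- lp - dat$L * (ls1 + ls2 + 0.5 * log1p(-rho^2)) -
          0.5 * cc * sum(Q)
        h1 <- cc * (e1 - rho * e2) / s1   # -dlogMVN/du1
        h2 <- cc * (e2 - rho * e1) / s2
        grad[map$z1] <- A - h1
        grad[map$z2] <- B - h2
        grad[map$lt0] <- grad[map$lt0] + sum(h1)
        grad[map$ll0] <- grad[map$ll0] + sum(h2)
        grad[map$ls1] <- sum(-1 + cc * (e1 - rho * e2) * e1) -
          s1^2 / sre^2 + 1
        grad[map$ls2] <- sum(-1 + cc * (e2 - rho * e1) * e2) -
          s2^2 / sre^2 + 1
        grad[map$rr] <- dat$L * rho + sum(e1 * e2) -
          rho * cc * sum(Q) - 2 * rho
      } else {
        lp <- lp - 0.5 * sum(z1^2) - 0.5 * sum(z2^2)
        grad[map$z1] <- A * s1 + B * s2 * rho - z1
        grad[map$z2] <- B * s2 * qr - z2
        grad[map$ls1] <- sum(A * z1) * s1 - s1^2 / sre^2 + 1
        grad[map$ls2] <- sum(B * (rho * z1 + qr * z2)) * s2 - s2^2 / sre^2 + 1
        g_rho <- s2 * sum(B * (z1 - (rho / qr) * z2))
        grad[map$rr] <- g_rho * (1 - rho^2) - 2 * rho
      }
    }
    list(lp = lp, grad = grad)
  }
}

chain_init <- function(dat, map, threshold, hierarchical, centered = TRUE) {
  q <- numeric(map$dim)
  q[map$lt0] <- log(max(stats::quantile(dat$y, 0.9), 0.1)) +
    stats::rnorm(1, 0, 0.2)
  q[map$ll0] <- log(1.2) + stats::rnorm(1, 0, 0.3)
  q[map$lsig] <- log(max(stats::sd(dat$y) * 0.5, 1e-3)) +
    stats::rnorm(1, 0, 0.3)
  if (threshold) {
    q[map$a_raw] <- log(0.2) + stats::rnorm(1, 0, 0.5)
    q[map$beta] <- stats::rnorm(1, 0, 0.2)
    q[map$t_raw] <- stats::rnorm(1, 0, 0.5)
  }
  if (hierarchical) {
    q[map$ls1] <- log(0.1) + stats::rnorm(1, 0, 0.3)
    q[map$ls2] <- log(0.1) + stats::rnorm(1, 0, 0.3)
    q[map$rr] <- stats::rnorm(1, 0, 0.3)
    if (centered) {
      q[map$z1] <- q[map$lt0] + stats::rnorm(dat$L, 0, 0.1)
      q[map$z2] <- q[map$ll0] + stats::rnorm(dat$L, 0, 0.1)
    } else {
      q[map$z1] <- stats::rnorm(dat$L, 0, 0.1)
      q[map$z2] <- stats::rnorm(dat$L, 0, 0.1)
    }
  }
  q
}

# unconstrained draws (matrix) -> natural-scale named draws (matrix)
natural_draws <- function(qm, map, levels, threshold, hierarchical,
                          centered = TRUE) {
  out <- list(theta0 = exp(qm[, map$lt0]), lambda0 = exp(qm[, map$ll0]))
  if (threshold) {
    out$alpha <- exp(qm[, map$a_raw])
    out$beta <- qm[, map$beta]
    out$psi_threshold <- -exp(qm[, map$t_raw])
  }
  out$sigma <- exp(qm[, map$lsig])
  if (hierarchical) {
    s1 <- exp(qm[, map$ls1]); s2 <- exp(qm[, map$ls2])
    rho <- tanh(qm[, map$rr]); qr <- sqrt(1 - rho^2)
    out$sd_log_theta0 <- s1
    out$sd_log_lambda0 <- s2
    out$re_correlation <- rho
    z1 <- qm[, map$z1, drop = FALSE]; z2 <- qm[, map$z2, drop = FALSE]
    if (centered) {
      u1 <- z1 - qm[, map$lt0]
      u2 <- z2 - qm[, map$ll0]
    } else {
      u1 <- z1 * s1
      u2 <- (z1 * rho + z2 * qr) * s2
    }
    colnames(u1) <- paste0("u_theta[", levels, "]")
    colnames(u2) <- paste0("u_lambda[", levels, "]")
    cbind(do.call(cbind, out), u1, u2)
  } else {
    do.call(cbind, out)
  }
}

#' Fit the hierarchical Delta-Psi changepoint model by MCMC
#'
#' Samples the posterior of the population parameters
#' (`theta0`, `lambda0`, `alpha`, `beta`, `psi_threshold`, `sigma`), the
#' random-effect scales/correlation and the per-level multiplicative offsets,
#' using Hamiltonian Monte Carlo with analytic gradients, dual-averaging
#' step-size adaptation and a warmup-adapted diagonal mass matrix. The
#' hierarchy places correlated normal random effects on `log theta0` and
#' `log lambda0` with one level per plant-year combination (non-centred
#' parameterization). With a single level the hierarchy degrades to a
#' fixed-effects fit with a warning.
#'
#' @param records a data frame of daily maximum records with columns
#'   `delta_psi_max` (MPa), `vpd_max_day` (kPa), `psi_soil_day` (MPa) and
#'   `level` (plant-year identifier), e.g. from [build_daily_records] or
#'   [simulate_daily_records].
#' @param config a [fit_config] object.
#' @return An object of class `psi_fit` with elements `draws` (array:
#'   iterations x chains x parameters, natural scale), `log_lik`
#'   (draws x observations pointwise log-likelihood), `mu`
#'   (draws x observations posterior mean surface), `rhat`, `records`,
#'   `levels`, `config`, `converged`, and sampler diagnostics.
#' @export
fit_posterior <- function(records, config = fit_config()) {
  dat <- model_data(records)
  hierarchical <- dat$L >= 2L
  if (!hierarchical) {
    warning("only one plant-year level: fitting without random effects")
  }
  threshold <- config$threshold
  centered <- identical(config$parameterization, "centered")
  map <- param_map(dat$L, threshold, hierarchical)
  lp_grad <- make_lp_grad(dat, map, config$prior, threshold, hierarchical,
                          centered)
  n_warmup <- floor(config$n_iterations * config$warmup_frac)
  n_keep <- config$n_iterations - n_warmup

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    q0 <- chain_init(dat, map, threshold, hierarchical, centered)
    chains[[ch]] <- hmc_chain(lp_grad, q0,
                              n_iter = config$n_iterations,
                              n_warmup = n_warmup,
                              n_leapfrog = config$n_leapfrog,
                              target_accept = config$target_accept,
                              seed = config$seed + 1000L * ch)
  }
  nat <- lapply(chains, function(chn)
    natural_draws(chn$draws, map, dat$levels, threshold, hierarchical,
                  centered))
  pnames <- colnames(nat[[1]])
  draws <- array(NA_real_, dim = c(n_keep, config$n_chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_along(nat)) draws[, ch, ] <- nat[[ch]]

  rhat <- if (config$n_chains >= 2L) compute_rhat(draws) else
    stats::setNames(rep(NA_real_, length(pnames)), pnames)

  flat <- do.call(rbind, nat)
  ll_mu <- pointwise_loglik(flat, dat, threshold, hierarchical)

  fit <- structure(list(
    draws = draws, log_lik = ll_mu$log_lik, mu = ll_mu$mu,
    rhat = rhat, records = records, levels = dat$levels, data = dat,
    config = config, threshold = threshold, hierarchical = hierarchical,
    accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
    n_divergent = vapply(chains, `[[`, integer(1), "n_divergent"),
    step_size = vapply(chains, `[[`, numeric(1), "eps")),
    class = "psi_fit")
  fit$converged <- all(is.finite(fit$rhat)) &&
    max(fit$rhat) < config$rhat_limit
  if (!fit$converged) {
    warning(sprintf("fit flagged as non-converged: max R-hat = %.4f",
                    suppressWarnings(max(fit$rhat, na.rm = TRUE))))
  }
  fit
}

# pointwise log-likelihood and mean surface for every stored draw
pointwise_loglik <- function(flat, dat, threshold, hierarchical) {
  S <- nrow(flat); n <- dat$n
  log_lik <- matrix(NA_real_, S, n)
  mu_m <- matrix(NA_real_, S, n)
  u1_cols <- paste0("u_theta[", dat$levels, "]")
  u2_cols <- paste0("u_lambda[", dat$levels, "]")
  for (s in seq_len(S)) {
    p <- flat[s, ]
    o1 <- if (hierarchical) p[u1_cols][dat$lev] else 0
    o2 <- if (hierarchical) p[u2_cols][dat$lev] else 0
    d <- if (threshold) pmax(0, p[["psi_threshold"]] - dat$P) else 0
    al <- if (threshold) p[["alpha"]] else 0
    be <- if (threshold) p[["beta"]] else 0
    th <- p[["theta0"]] * exp(o1 - al * d)
    lam <- p[["lambda0"]] * exp(o2 - be * d)
    mu <- th * (1 - exp(-lam * dat$V))
    mu_m[s, ] <- mu
    log_lik[s, ] <- stats::dnorm(dat$y, mu, p[["sigma"]], log = TRUE)
  }
  list(log_lik = log_lik, mu = mu_m)
}

#' @export
print.psi_fit <- function(x, ...) {
  cat(sprintf("Delta-Psi model fit: %d records, %d plant-year levels\n",
              x$data$n, x$data$L))
  cat(sprintf("  %d chains x %d iterations (%d kept); model: %s, %s\n",
              x$config$n_chains, x$config$n_iterations, dim(x$draws)[1],
              if (x$threshold) "changepoint" else "no-threshold",
              if (x$hierarchical) "hierarchical" else "fixed-effects"))
  cat(sprintf("  max R-hat %.4f (%s); mean acceptance %.2f; divergences %d\n",
              suppressWarnings(max(x$rhat, na.rm = TRUE)),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              mean(x$accept_rate), sum(x$n_divergent)))
  print(summary(x), ...)
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object a `psi_fit`.
#' @param pars parameters to summarize; defaults to the population-level
#'   parameters (random-effect offsets excluded).
#' @param ... unused.
#' @return data frame with posterior mean, sd, central 95% interval,
#'   median and R-hat per parameter.
#' @export
summary.psi_fit <- function(object, pars = NULL, ...) {
  all_pars <- dimnames(object$draws)[[3]]
  if (is.null(pars)) pars <- grep("^u_", all_pars, invert = TRUE, value = TRUE)
  out <- do.call(rbind, lapply(pars, function(pn) {
    d <- as.vector(object$draws[, , pn])
    data.frame(parameter = pn, mean = mean(d), sd = stats::sd(d),
               q2.5 = stats::quantile(d, 0.025, names = FALSE),
               median = stats::median(d),
               q97.5 = stats::quantile(d, 0.975, names = FALSE),
               rhat = unname(object$rhat[pn]))
  }))
  rownames(out) <- NULL
  out
}

#' Central posterior credible intervals
#'
#' @param fit a `psi_fit`.
#' @param pars parameter names (default: population-level parameters).
#' @param prob interval mass (default 0.95).
#' @return matrix with `lower` and `upper` columns.
#' @export
posterior_interval <- function(fit, pars = NULL, prob = 0.95) {
  all_pars <- dimnames(fit$draws)[[3]]
  if (is.null(pars)) pars <- grep("^u_", all_pars, invert = TRUE, value = TRUE)
  a <- (1 - prob) / 2
  t(vapply(pars, function(pn) {
    stats::quantile(as.vector(fit$draws[, , pn]), c(a, 1 - a), names = FALSE)
  }, numeric(2))) -> m
  colnames(m) <- c("lower", "upper")
  m
}

#' Population parameters at posterior summaries
#'
#' Collapses the posterior to a single [population_params] vector using
#' posterior means (default) or medians, e.g. to drive [gc_surface].
#'
#' @param fit a `psi_fit`.
#' @param statistic "mean" or "median".
#' @return a [population_params] object.
#' @export
posterior_params <- function(fit, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "mean") mean else stats::median
  g <- function(pn, default = 0) {
    if (pn %in% dimnames(fit$draws)[[3]]) f(as.vector(fit$draws[, , pn]))
    else default
  }
  population_params(theta0 = g("theta0"), lambda0 = g("lambda0"),
                    alpha = g("alpha"), beta = g("beta"),
                    psi_threshold = min(0, g("psi_threshold")),
                    sigma = g("sigma"))
}

## ---- PSIS-LOO ------------------------------------------------------------

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 posterior-mean
# estimator, with the weak k prior used by standard PSIS implementations).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior_bs * xstar)
  # profile likelihood over the grid b = -k/sigma: the conditional shape
  # MLE is k(b) = mean log(1 - b x) and l(b) = n [log(-b/k) - k - 1]
  k <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  l <- ifelse(b / k < 0, n * (log(-b / k) - k - 1), -Inf)
  w <- exp(l - max(l)); w <- w / sum(w)
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  k_reg <- (n * k_hat + 5) / (n + 10)  # shrink toward 0.5 with 10 pseudo-obs
  list(k = k_reg, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance ratios. Returns the smoothed
# (unnormalized) log weights and the Pareto k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  m <- max(lw)
  tail_len <- as.integer(ceiling(min(0.2 * S, 3 * sqrt(S))))
  if (tail_len < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1):S]
  cut <- lw[ord[S - tail_len]]
  exc <- exp(lw[tail_idx] - m) - exp(cut - m)
  if (all(exc <= 0) || stats::sd(exc) == 0) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  pr <- (rank(lw[tail_idx], ties.method = "first") - 0.5) / tail_len
  sm <- exp(cut - m) + vapply(pr, qgpd, numeric(1), k = fit$k, sigma = fit$sigma)
  if (any(!is.finite(sm)) || any(sm <= 0)) return(list(lw = lw, k = fit$k))
  lw_new <- lw
  lw_new[tail_idx] <- pmin(log(sm) + m, m)  # truncate at raw maximum
  list(lw = lw_new, k = fit$k)
}

#' PSIS-LOO cross-validation for a fitted model
#'
#' Pareto-smoothed importance-sampling approximation to exact
#' leave-one-out cross-validation, computed from the stored pointwise
#' log-likelihood matrix. Reports the expected log pointwise predictive
#' density (`elpd_loo`), its standard error, and the Pareto-k diagnostic
#' per observation; a warning is attached when more than 5% of
#' observations exceed k = 0.7.
#'
#' @param fit a `psi_fit`.
#' @return list of class `psi_loo` with `elpd_loo`, `se`, `pointwise`,
#'   `khat`, `frac_high_k`, and per-observation smoothed weights.
#' @export
compute_loo <- function(fit) {
  ll <- fit$log_lik
  n <- ncol(ll)
  elpd <- numeric(n); khat <- numeric(n)
  lw_smooth <- matrix(NA_real_, nrow(ll), n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
    elpd[i] <- lse(sm$lw + ll[, i]) - lse(sm$lw)
    khat[i] <- sm$k
    lw_smooth[, i] <- sm$lw
  }
  frac_high <- mean(khat > 0.7, na.rm = TRUE)
  if (is.finite(frac_high) && frac_high > 0.05) {
    warning(sprintf("%.1f%% of observations have Pareto k > 0.7; ",
                    100 * frac_high),
            "PSIS-LOO estimates may be unreliable")
  }
  structure(list(elpd_loo = sum(elpd), se = sqrt(n * stats::var(elpd)),
                 pointwise = elpd, khat = khat, frac_high_k = frac_high,
                 lw_smooth = lw_smooth),
            class = "psi_loo")
}

#' @export
print.psi_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.1f (SE %.1f), n = %d\n",
              x$elpd_loo, x$se, length(x$pointwise)))
  cat(sprintf("  Pareto k > 0.7 for %.1f%% of observations\n",
              100 * x$frac_high_k))
  invisible(x)
}

#' LOO R-squared with 95% interval
#'
#' Variance explained by the leave-one-out predictive means:
#' `1 - var(y - yhat_loo) / var(y)`, with `yhat_loo` the PSIS-weighted
#' posterior mean of the latent surface for each held-out observation.
#' The interval is a Bayesian bootstrap over observations (Dirichlet
#' weights), reflecting sampling uncertainty in the variance ratio.
#'
#' @param fit a `psi_fit`.
#' @param loo optionally, a precomputed [compute_loo] result.
#' @param n_boot bootstrap replicates for the interval.
#' @param seed seed for the bootstrap.
#' @return list with `estimate`, `ci` (length-2), and `yhat_loo`.
#' @export
compute_loo_r2 <- function(fit, loo = NULL, n_boot = 2000L, seed = 1L) {
  if (is.null(loo)) loo <- suppressWarnings(compute_loo(fit))
  y <- fit$data$y
  n <- length(y)
  yhat <- vapply(seq_len(n), function(i) {
    w <- exp(loo$lw_smooth[, i] - max(loo$lw_smooth[, i]))
    sum(w * fit$mu[, i]) / sum(w)
  }, numeric(1))
  e <- y - yhat
  r2 <- 1 - stats::var(e) / stats::var(y)
  set.seed(seed)
  wvar <- function(x, w) sum(w * (x - sum(w * x))^2) / (1 - sum(w^2))
  boot <- replicate(n_boot, {
    w <- stats::rgamma(n, 1); w <- w / sum(w)
    1 - wvar(e, w) / wvar(y, w)
  })
  list(estimate = r2, ci = stats::quantile(boot, c(0.025, 0.975),
                                           names = FALSE),
       yhat_loo = yhat)
}

#' Bayesian R-squared with 95% interval
#'
#' The draw-wise proportion of explained variance
#' `var(mu_s) / (var(mu_s) + sigma_s^2)` (Gelman et al. 2019), summarized
#' by its posterior mean and central 95% interval.
#'
#' @param fit a `psi_fit`.
#' @return list with `estimate`, `ci`, and the per-draw values.
#' @export
bayes_r2 <- function(fit) {
  sig <- as.vector(fit$draws[, , "sigma"])
  vmu <- apply(fit$mu, 1, stats::var)
  r2 <- vmu / (vmu + sig^2)
  list(estimate = mean(r2),
       ci = stats::quantile(r2, c(0.025, 0.975), names = FALSE),
       draws = r2)
}

#' Posterior-predictive interval coverage
#'
#' Fraction of observed records falling inside the central
#' posterior-predictive interval of mass `prob`. Predictive draws are the
#' latent surface draws plus Gaussian residual noise; a well-calibrated
#' fit on well-specified data has coverage near `prob`.
#'
#' @param fit a `psi_fit`.
#' @param prob interval mass (default 0.95).
#' @param seed seed for the predictive noise draws.
#' @return scalar coverage fraction in `[0, 1]`.
#' @export
ppc_coverage <- function(fit, prob = 0.95, seed = 1L) {
  set.seed(seed)
  S <- nrow(fit$mu); n <- ncol(fit$mu)
  sig <- as.vector(fit$draws[, , "sigma"])
  a <- (1 - prob) / 2
  inside <- vapply(seq_len(n), function(i) {
    yrep <- fit$mu[, i] + stats::rnorm(S, 0, sig)
    qs <- stats::quantile(yrep, c(a, 1 - a), names = FALSE)
    fit$data$y[i] >= qs[1] && fit$data$y[i] <= qs[2]
  }, logical(1))
  mean(inside)
}

#' Full diagnostics report for a fitted model
#'
#' Assembles the diagnostic suite: per-parameter R-hat, PSIS-LOO
#' (elpd and SE), LOO R-squared and Bayesian R-squared with 95%
#' intervals, posterior-predictive 95% coverage, and residual summaries
#' by plant (mean and mean absolute residual of the posterior-mean
#' prediction).
#'
#' @param fit a `psi_fit`.
#' @param seed seed for the stochastic components (coverage, bootstrap).
#' @return list of class `psi_diagnostics`.
#' @export
diagnostics_report <- function(fit, seed = 1L) {
  loo <- suppressWarnings(compute_loo(fit))
  loo_r2 <- compute_loo_r2(fit, loo = loo, seed = seed)
  br2 <- bayes_r2(fit)
  cov95 <- ppc_coverage(fit, prob = 0.95, seed = seed)
  resid <- fit$data$y - colMeans(fit$mu)
  plant <- if ("plant_id" %in% names(fit$records))
    as.character(fit$records$plant_id) else as.character(fit$records$level)
  by_plant <- do.call(rbind, lapply(split(resid, plant), function(r)
    data.frame(mean_resid = mean(r), mean_abs_resid = mean(abs(r)),
               n = length(r))))
  by_plant$plant_id <- rownames(by_plant)
  rownames(by_plant) <- NULL
  structure(list(rhat = fit$rhat, converged = fit$converged,
                 loo_elpd = loo$elpd_loo, loo_se = loo$se,
                 pareto_k_frac_high = loo$frac_high_k,
                 loo_r2 = loo_r2$estimate, loo_r2_ci = loo_r2$ci,
                 bayes_r2 = br2$estimate, bayes_r2_ci = br2$ci,
                 ppc_coverage_95 = cov95,
                 residuals_by_plant = by_plant),
            class = "psi_diagnostics")
}

#' @export
print.psi_diagnostics <- function(x, ...) {
  cat("Model diagnostics\n")
  cat(sprintf("  max R-hat        %.4f (%s)\n",
              suppressWarnings(max(x$rhat, na.rm = TRUE)),
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat(sprintf("  elpd_loo         %.1f (SE %.1f)\n", x$loo_elpd, x$loo_se))
  cat(sprintf("  LOO R2           %.3f (95%% CI %.3f-%.3f)\n",
              x$loo_r2, x$loo_r2_ci[1], x$loo_r2_ci[2]))
  cat(sprintf("  Bayesian R2      %.3f (95%% CI %.3f-%.3f)\n",
              x$bayes_r2, x$bayes_r2_ci[1], x$bayes_r2_ci[2]))
  cat(sprintf("  95%% PPC coverage %.3f\n", x$ppc_coverage_95))
  invisible(x)
}
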