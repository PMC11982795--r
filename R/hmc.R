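# Hamiltonian Monte Carlo engine used by fit_posterior().
#
# Static HMC with jittered path length, dual-averaging step-size adaptation
# (Hoffman & Gelman 2014, Algorithm 5) and a diagonal mass matrix re-estimated
# twice during warmup. Generic over the target: `lp_grad(q)` must return
# list(lp = <scalar log density>, grad = <gradient vector>). Kept internal;
# the model-facing interface is fit_posterior().

find_reasonable_epsilon <- function(lp_grad, q, inv_mass) {
  eps <- 0.1
  s <- lp_grad(q)
  p <- stats::rnorm(length(q)) / sqrt(inv_mass)
  h0 <- s$lp - 0.5 * sum(p^2 * inv_mass)
  step <- leapfrog(lp_grad, q, p, eps, inv_mass, s$grad)
  h1 <- if (is.finite(step$lp)) step$lp - 0.5 * sum(step$p^2 * inv_mass) else -Inf
  a <- if (is.finite(h1) && (h1 - h0) > log(0.5)) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^a
    step <- leapfrog(lp_grad, q, p, eps, inv_mass, s$grad)
    h1 <- if (is.finite(step$lp)) step$lp - 0.5 * sum(step$p^2 * inv_mass) else -Inf
    if (a * (h1 - h0) <= a * log(0.5)) break
  }
  eps
}

leapfrog <- function(lp_grad, q, p, eps, inv_mass, grad) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * inv_mass * p
  s <- lp_grad(q)
  if (!is.finite(s$lp) || any(!is.finite(s$grad))) {
    return(list(q = q, p = p, lp = -Inf, grad = s$grad))
  }
  p <- p + 0.5 * eps * s$grad
  list(q = q, p = p, lp = s$lp, grad = s$grad)
}

# One chain. Returns list(draws = matrix (n_keep x dim), accept_rate, eps).
hmc_chain <- function(lp_grad, q0, n_iter, n_warmup,
                      n_leapfrog = 12L, target_accept = 0.8,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dim <- length(q0)
  q <- q0
  s <- lp_grad(q)
  if (!is.finite(s$lp)) stop("initial point has non-finite log density")
  inv_mass <- rep(1, dim)

  # dual-averaging state
  da_init <- function(eps) {
    list(mu = log(10 * eps), log_eps = log(eps), log_eps_bar = 0,
         h_bar = 0, count = 0, gamma = 0.05, t0 = 10, kappa = 0.75)
  }
  da_update <- function(da, accept_prob) {
    da$count <- da$count + 1
    w <- 1 / (da$count + da$t0)
    da$h_bar <- (1 - w) * da$h_bar + w * (target_accept - accept_prob)
    da$log_eps <- da$mu - sqrt(da$count) / da$gamma * da$h_bar
    m <- da$count^(-da$kappa)
    da$log_eps_bar <- m * da$log_eps + (1 - m) * da$log_eps_bar
    da
  }

  eps <- find_reasonable_epsilon(lp_grad, q, inv_mass)
  da <- da_init(eps)

  # mass-matrix re-estimation checkpoints inside warmup
  ckpt1 <- floor(0.5 * n_warmup)
  ckpt2 <- floor(0.9 * n_warmup)
  wsum <- numeric(dim); wsum2 <- numeric(dim); wn <- 0L

  draws <- matrix(NA_real_, nrow = n_iter - n_warmup, ncol = dim)
  n_accept <- 0
  n_div <- 0L

  for (it in seq_len(n_iter)) {
    p0 <- stats::rnorm(dim) / sqrt(inv_mass)
    h0 <- s$lp - 0.5 * sum(p0^2 * inv_mass)
    L <- sample(max(1L, floor(0.5 * n_leapfrog)):ceiling(1.5 * n_leapfrog), 1L)
    qq <- q; pp <- p0; gg <- s$grad; lp_new <- s$lp
    diverged <- FALSE
    for (l in seq_len(L)) {
      st <- leapfrog(lp_grad, qq, pp, eps, inv_mass, gg)
      if (!is.finite(st$lp)) { diverged <- TRUE; break }
      qq <- st$q; pp <- st$p; gg <- st$grad; lp_new <- st$lp
    }
    if (diverged) {
      accept_prob <- 0
      n_div <- n_div + 1L
    } else {
      h1 <- lp_new - 0.5 * sum(pp^2 * inv_mass)
      accept_prob <- min(1, exp(h1 - h0))
      if (stats::runif(1) < accept_prob) {
        q <- qq
        s <- list(lp = lp_new, grad = gg)
        if (it > n_warmup) n_accept <- n_accept + 1
      }
    }

    if (it <= n_warmup) {
      da <- da_update(da, accept_prob)
      eps <- exp(da$log_eps)
      if (it > floor(0.25 * n_warmup)) {
        wsum <- wsum + q; wsum2 <- wsum2 + q^2; wn <- wn + 1L
      }
      if ((it == ckpt1 || it == ckpt2) && wn >= 20L) {
        v <- (wsum2 - wsum^2 / wn) / (wn - 1)
        # regularize toward unit scale, as Stan does
        v <- (wn / (wn + 5)) * v + (5 / (wn + 5)) * 1e-3
        v[v <= 0 | !is.finite(v)] <- 1
        inv_mass <- v
        wsum[] <- 0; wsum2[] <- 0; wn <- 0L
        eps <- find_reasonable_epsilon(lp_grad, q, inv_mass)
        da <- da_init(eps)
      }
      if (it == n_warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- q
    }
  }
  list(draws = draws,
       accept_rate = n_accept / max(1L, n_iter - n_warmup),
       eps = eps, n_divergent = n_div)
}

#' Rank-normalized split R-hat convergence diagnostic
#'
#' The improved potential-scale-reduction statistic of Vehtari et al. (2021):
#' chains are split in half, all draws are rank-normalized via the inverse
#' normal transform, and the classic between/within-chain variance ratio is
#' computed on the transformed draws. The folded version (applied to absolute
#' deviations from the median, sensitive to scale mismatch) is computed too
#' and the maximum of the two is returned.
#'
#' @param draws a matrix of posterior draws, iterations x chains (>= 2
#'   chains), or a 3-d array iterations x chains x parameters.
#' @return a scalar R-hat (or named vector, one per parameter, for an
#'   array input). `NA` with a warning when the draws are constant.
#' @export
compute_rhat <- function(draws) {
  if (length(dim(draws)) == 3L) {
    out <- apply(draws, 3, compute_rhat)
    return(out)
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("R-hat requires at least 2 chains")
  if (stats::sd(draws) == 0 || !is.finite(stats::sd(draws))) {
    warning("draws have zero variance; R-hat is undefined")
    return(NA_real_)
  }
  half <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  rhat_basic <- function(x) {
    n <- nrow(x); m <- ncol(x)
    mns <- colMeans(x)
    b <- n * stats::var(mns)
    w <- mean(apply(x, 2, stats::var))
    if (w == 0) return(NA_real_)
    sqrt(((n - 1) / n * w + b / n) / w)
  }
  znorm <- function(x) {
    r <- rank(x, ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
    matrix(z, nrow = nrow(x))
  }
  bulk <- rhat_basic(znorm(split))
  folded <- rhat_basic(znorm(abs(split - stats::median(split))))
  max(bulk, folded, na.rm = TRUE)
}
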