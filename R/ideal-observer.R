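# Ideal Bayesian observer: posterior category odds by deterministic
# quadrature over the unknown category means (and, optionally, the shared
# category SD under a Jeffreys prior), restricted to mu_A < mu_B.
#
# The per-category sample likelihood only depends on (n, mean, ss), so the
# integrand is evaluated on grids from sufficient statistics. The mu_A < mu_B
# constraint is handled with cumulative sums over the mean grid, keeping each
# odds evaluation O(G_mu * G_sigma).

ideal_grids <- function(state, params, n_mu = 121, n_sigma = 61,
                        sigma_lo = 1, sigma_hi = 50) {
  xs <- c(state$stats_A$samples, state$stats_B$samples)
  if (length(xs) == 0) {
    stop("ideal observer needs at least one observed sample", call. = FALSE)
  }
  sig_hat <- if (length(xs) >= 3) max(stats::sd(xs), 2) else 10
  mu <- seq(min(xs) - 4 * sig_hat, max(xs) + 4 * sig_hat, length.out = n_mu)
  if (!is.null(params$sigma_cat)) {
    sigma <- params$sigma_cat
    w_log_sigma <- 0  # conditioning on a known SD: no integral, no prior
  } else {
    sigma <- exp(seq(log(sigma_lo), log(sigma_hi), length.out = n_sigma))
    # trapezoid weights in log(sigma); the Jeffreys density 1/sigma times the
    # Jacobian sigma d(log sigma) makes the measure uniform on the log grid
    h <- diff(log(sigma))
    w <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
    w_log_sigma <- log(w)
  }
  list(mu = mu, sigma = sigma, w_log_sigma = w_log_sigma)
}

# log-likelihood of one category's samples on the (mu, sigma) grid,
# as an n_mu x n_sigma matrix; flat (0) if the category has no samples yet
category_loglik_grid <- function(stats, mu, sigma) {
  if (stats$n == 0L) {
    return(matrix(0, length(mu), length(sigma)))
  }
  d2 <- outer((mu - stats$mean)^2 * stats$n + stats$ss, 2 * sigma^2, "/")
  -d2 - rep(stats$n * log(sigma), each = length(mu))
}

#' Posterior category odds of the ideal Bayesian observer
#'
#' Computes the posterior odds that a new measurement belongs to category A
#' rather than B, given all previously observed samples, marginalizing over
#' the unknown category means (flat prior on the region `mu_A < mu_B`) and,
#' unless `params$sigma_cat` is supplied, over the shared category SD under a
#' Jeffreys prior truncated to `[1, 50]` degrees. Odds greater than 1 favor
#' category A. Integration is by deterministic trapezoid quadrature on fixed
#' grids, so results are reproducible and testable by resolution doubling.
#'
#' @param state a `criterion_state` whose sufficient statistics hold the
#'   sample history (at least one sample in total; an empty category
#'   contributes a flat likelihood).
#' @param x_new the new measurement in degrees.
#' @param params list; optional `sigma_cat` conditions on a known category
#'   SD, optional `p_A` prior category probability (default 0.5).
#' @param n_mu,n_sigma grid sizes for the means and the SD.
#' @return `ideal_posterior_odds()` returns the odds ratio;
#'   `ideal_log_posterior_odds()` its logarithm.
#' @export
ideal_posterior_odds <- function(state, x_new, params = list(),
                                 n_mu = 121, n_sigma = 61) {
  exp(ideal_log_posterior_odds(state, x_new, params, n_mu, n_sigma))
}

#' @rdname ideal_posterior_odds
#' @export
ideal_log_posterior_odds <- function(state, x_new, params = list(),
                                     n_mu = 121, n_sigma = 61) {
  g <- ideal_grids(state, params, n_mu = n_mu, n_sigma = n_sigma)
  p_A <- if (is.null(params$p_A)) 0.5 else params$p_A
  la <- category_loglik_grid(state$stats_A, g$mu, g$sigma)
  lb <- category_loglik_grid(state$stats_B, g$mu, g$sigma)
  # log N(x_new; mu, sigma) up to the shared 1/sqrt(2 pi) constant
  lf <- -outer((g$mu - x_new)^2, 2 * g$sigma^2, "/") -
    rep(log(g$sigma), each = length(g$mu))
  sc_a <- max(la); sc_b <- max(lb); sc_f <- max(lf)
  A <- exp(la - sc_a); B <- exp(lb - sc_b); F_ <- exp(lf - sc_f)
  # mu_A < mu_B: triangular sums via cumulative sums over the mean grid
  # (rows); the diagonal enters with half weight, which keeps the
  # discretization of the constrained integral second-order accurate
  cum_fa <- apply(F_ * A, 2, cumsum)   # sum_{i <= j} f_i a_i
  cum_a <- apply(A, 2, cumsum)
  # numerator: sum_{i < j} f_i a_i b_j ; denominator: sum_{i < j} a_i f_j b_j
  num_s <- colSums(B * (cum_fa - 0.5 * F_ * A))
  den_s <- colSums(F_ * B * (cum_a - 0.5 * A))
  lw <- g$w_log_sigma
  log_num <- log_sum_exp(log(num_s) + lw)
  log_den <- log_sum_exp(log(den_s) + lw)
  if (!is.finite(log_num) && !is.finite(log_den)) {
    stop("posterior odds numerically undefined (all mass underflowed)",
         call. = FALSE)
  }
  log(p_A) - log(1 - p_A) + log_num - log_den
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Criterion of the ideal Bayesian observer
#'
#' The optimal criterion is the measurement value at which the posterior
#' odds equal one; responses then follow the sign of the measurement
#' relative to it. Found by bracketed root-finding on the log odds between
#' the two per-category sample means (the bracket is widened if needed).
#'
#' @inheritParams ideal_posterior_odds
#' @return Criterion orientation in degrees.
#' @export
ideal_criterion <- function(state, params = list(), n_mu = 121, n_sigma = 61) {
  if (state$stats_A$n == 0L || state$stats_B$n == 0L) {
    stop("ideal criterion requires at least one sample from each category",
         call. = FALSE)
  }
  f <- function(x) ideal_log_posterior_odds(state, x, params, n_mu, n_sigma)
  lo <- state$stats_A$mean
  hi <- state$stats_B$mean
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  if (lo == hi) { lo <- lo - 1e-3; hi <- hi + 1e-3 }
  flo <- f(lo); fhi <- f(hi)
  width <- max(hi - lo, 5)
  tries <- 0
  while (sign(flo) == sign(fhi) && tries < 8) {
    lo <- lo - width; hi <- hi + width
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1
  }
  if (sign(flo) == sign(fhi)) {
    stop("no sign change in posterior log odds; cannot bracket the criterion",
         call. = FALSE)
  }
  stats::uniroot(f, lower = lo, upper = hi, f.lower = flo, f.upper = fhi,
                 tol = 1e-4)$root
}
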