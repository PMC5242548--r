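#' The observer-model registry
#'
#' Six trial-by-trial criterion-learning rules are implemented. Each rule
#' maintains running estimates of the two category means (or an internal
#' criterion) and proposes a decision criterion for the next trial:
#'
#' * `ideal_bayes`: full Bayesian observer; computes posterior category odds
#'   marginalizing over the unknown category means and SD (static mode only).
#' * `bayes_selection`: point-estimate Bayesian observer; running arithmetic
#'   mean of all samples seen from each category.
#' * `ewma`: exponentially weighted moving average of each category's
#'   samples, recency weight `alpha`.
#' * `kalman`: Bayesian mean tracker for a Gaussian random walk; trial-specific
#'   gain determined by the ratio `r = sigma_random^2 / sigma_cat^2`.
#' * `delta_rule`: reinforcement learning; moves an internal criterion a
#'   fraction `beta` toward the stimulus after negative feedback only.
#' * `limited_memory`: each category mean estimate is the most recent sample
#'   from that category.
#'
#' @return A tibble with one row per model: `model_id`, `label`, the modes
#'   (static/dynamic) it supports, and its free parameters in the covert and
#'   overt tasks (noise SD plus any learning parameter).
#' @examples
#' model_registry()
#' @export
model_registry <- function() {
  tibble::tibble(
    model_id = c("ideal_bayes", "bayes_selection", "ewma", "kalman",
                 "delta_rule", "limited_memory"),
    label = c("Ideal Bayesian", "Bayesian model selection",
              "Exponentially weighted moving average", "Kalman filter",
              "Reinforcement learning (delta rule)", "Limited memory"),
    static = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    dynamic = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    covert_free = list(c("sigma_v", "sigma_cat"), "sigma_v",
                       c("sigma_v", "alpha"), c("sigma_v", "r"),
                       c("sigma_v", "beta"), "sigma_v"),
    overt_free = list(c("sigma_a", "sigma_cat"), "sigma_a",
                      c("sigma_a", "alpha"), c("sigma_a", "r"),
                      c("sigma_a", "beta"), "sigma_a")
  )
}

.model_ids <- c("ideal_bayes", "bayes_selection", "ewma", "kalman",
                "delta_rule", "limited_memory")
.static_models <- setdiff(.model_ids, "kalman")
.dynamic_models <- setdiff(.model_ids, c("ideal_bayes", "bayes_selection"))

assert_model_id <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% .model_ids) {
    stop("unknown model_id; must be one of: ",
         paste(.model_ids, collapse = ", "), call. = FALSE)
  }
  model_id
}

#' Create a fresh observer state
#'
#' The state carries everything a learning rule needs between trials:
#' per-category mean estimates and counts, the delta-rule internal criterion,
#' Kalman posterior variances, and (for the Bayesian models) per-category
#' sufficient statistics and sample lists.
#'
#' @param model_id one of the ids in [model_registry()].
#' @param z_init initial internal criterion in degrees (delta rule).
#' @return A list of class `criterion_state`.
#' @export
new_criterion_state <- function(model_id, z_init = 0) {
  assert_model_id(model_id)
  structure(list(
    model_id = model_id,
    mu_A = NA_real_, mu_B = NA_real_,
    n_A = 0L, n_B = 0L,
    z = z_init,
    sig_tot_sq_A = 0, sig_tot_sq_B = 0,
    kappa_A = NA_real_, kappa_B = NA_real_,
    stats_A = list(n = 0L, mean = NA_real_, ss = 0, samples = numeric(0)),
    stats_B = list(n = 0L, mean = NA_real_, ss = 0, samples = numeric(0))
  ), class = "criterion_state")
}

update_suffstats <- function(s, x) {
  n1 <- s$n + 1L
  if (s$n == 0L) {
    list(n = n1, mean = x, ss = 0, samples = x)
  } else {
    d <- arc_diff(x, s$mean)
    mean1 <- wrap_orientation(s$mean + d / n1)
    list(n = n1, mean = mean1, ss = s$ss + d * arc_diff(x, mean1),
         samples = c(s$samples, x))
  }
}

#' Running-mean update (Bayesian model selection)
#'
#' Recursive form of the sample mean: the new estimate is the old estimate
#' plus `1/(n+1)` of the prediction error. Reproduces the batch mean of all
#' consumed samples exactly.
#'
#' @param state a `criterion_state`.
#' @param x stimulus orientation in degrees.
#' @param category `"A"` or `"B"`.
#' @return The updated state.
#' @export
running_mean_update <- function(state, x, category) {
  f <- paste0("mu_", category); nf <- paste0("n_", category)
  n <- state[[nf]]
  state[[f]] <- if (n == 0L) x else
    wrap_orientation(state[[f]] + arc_diff(x, state[[f]]) / (n + 1))
  state[[nf]] <- n + 1L
  sfld <- paste0("stats_", category)
  state[[sfld]] <- update_suffstats(state[[sfld]], x)
  state
}

#' Exponentially weighted moving-average update
#'
#' `mu <- alpha * x + (1 - alpha) * mu` for the presented category only; the
#' other category's estimate is untouched. The first sample of a category
#' initializes its estimate. `alpha = 1` reproduces the limited-memory rule.
#'
#' @inheritParams running_mean_update
#' @param alpha recency weight in (0, 1]; boundary 1 allowed (limited memory).
#' @return The updated state.
#' @export
ewma_update <- function(state, x, category, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  f <- paste0("mu_", category); nf <- paste0("n_", category)
  state[[f]] <- if (state[[nf]] == 0L || alpha == 1) x else
    wrap_orientation(state[[f]] + alpha * arc_diff(x, state[[f]]))
  state[[nf]] <- state[[nf]] + 1L
  state
}

#' Kalman-filter update for one category mean
#'
#' Bayesian mean tracking under an assumed Gaussian random walk with step
#' variance `sigma_random^2` and category variance `sigma_cat^2`. The gain
#' sequence depends only on their ratio `r`. Initialization: the first sample
#' of a category sets its estimate with posterior variance zero.
#'
#' @inheritParams running_mean_update
#' @param r ratio `sigma_random^2 / sigma_cat^2` (positive).
#' @return The updated state.
#' @export
kalman_update <- function(state, x, category, r) {
  stopifnot(r > 0)
  f <- paste0("mu_", category); nf <- paste0("n_", category)
  vf <- paste0("sig_tot_sq_", category); kf <- paste0("kappa_", category)
  if (state[[nf]] == 0L) {
    state[[f]] <- x
    state[[vf]] <- 0
    state[[kf]] <- 0
  } else {
    # work in units of sigma_cat^2 = 1, so sigma_random^2 = r
    v <- (1 - state[[kf]]) * state[[vf]] + r
    kappa <- v / (v + 1)
    state[[f]] <- wrap_orientation(state[[f]] + kappa * arc_diff(x, state[[f]]))
    state[[vf]] <- v
    state[[kf]] <- kappa
  }
  state[[nf]] <- state[[nf]] + 1L
  state
}

#' Delta-rule (reinforcement learning) update
#'
#' The internal criterion is left untouched after correct feedback and moved
#' a fraction `beta` toward the stimulus after an error.
#'
#' @inheritParams running_mean_update
#' @param feedback_correct logical; was the trial's feedback positive?
#' @param beta learning rate in [0, 1].
#' @return The updated state.
#' @export
delta_rule_update <- function(state, x, feedback_correct, beta) {
  stopifnot(beta >= 0, beta <= 1)
  if (!feedback_correct) {
    state$z <- wrap_orientation(state$z + beta * arc_diff(x, state$z))
  }
  state
}

#' Limited-memory update
#'
#' The presented category's mean estimate is replaced by the sample just
#' seen; nothing else is retained.
#'
#' @inheritParams running_mean_update
#' @return The updated state.
#' @export
limited_memory_update <- function(state, x, category) {
  f <- paste0("mu_", category); nf <- paste0("n_", category)
  state[[f]] <- x
  state[[nf]] <- state[[nf]] + 1L
  state
}

#' Criterion halfway between the two category-mean estimates
#'
#' @param state a `criterion_state` with both `mu_A` and `mu_B` defined.
#' @return Criterion orientation in degrees.
#' @export
midpoint_criterion <- function(state) {
  if (is.na(state$mu_A) || is.na(state$mu_B)) {
    stop("both category estimates must be defined before a midpoint criterion",
         call. = FALSE)
  }
  wrap_orientation(state$mu_A + arc_diff(state$mu_B, state$mu_A) / 2)
}

#' Probability of a category-A response
#'
#' The observer responds A when the noisy measurement `X ~ N(S, sigma_v)`
#' falls clockwise of the criterion, giving the probit choice rule
#' `P(A) = Phi((z - S) / sigma_v)`.
#'
#' @param criterion criterion orientation(s) in degrees.
#' @param stimulus stimulus orientation(s) in degrees.
#' @param sigma_v sensory noise SD in degrees; `0` gives a step function
#'   (probability 0.5 at equality).
#' @return Probability of responding A (vectorized).
#' @export
covert_choice_probability <- function(criterion, stimulus, sigma_v) {
  stopifnot(sigma_v >= 0)
  d <- arc_diff(criterion, stimulus)
  if (sigma_v == 0) {
    ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5))
  } else {
    stats::pnorm(d / sigma_v)
  }
}

#' Convert between the EWMA weight and its time constant
#'
#' The exponential time constant (in trials) of the weight sequence
#' `1, 1-alpha, (1-alpha)^2, ...` is `tau = -1 / log(1 - alpha)`.
#'
#' @param alpha recency weight in (0, 1).
#' @param tau time constant in trials.
#' @return `alpha_to_tau()` returns `tau`; `tau_to_alpha()` its inverse.
#'   Boundary values map to `Inf`/`0` as limits.
#' @examples
#' alpha_to_tau(1 - exp(-1)) # 1 trial
#' @export
alpha_to_tau <- function(alpha) {
  stopifnot(all(alpha >= 0), all(alpha <= 1))
  ifelse(alpha == 1, 0, ifelse(alpha == 0, Inf, -1 / log(1 - alpha)))
}

#' @rdname alpha_to_tau
#' @export
tau_to_alpha <- function(tau) {
  stopifnot(all(tau >= 0))
  ifelse(tau == 0, 1, ifelse(is.infinite(tau), 0, 1 - exp(-1 / tau)))
}

#' Kalman gain sequence and its fixed point
#'
#' The gain recursion `kappa_n = v_n / (v_n + 1)`,
#' `v_n = (1 - kappa_{n-1}) v_{n-1} + r` (variances in units of the category
#' variance) starts at `v_1 = 0` and converges to the positive root of
#' `kappa^2 + r * kappa - r = 0`.
#'
#' @param n_obs number of category observations.
#' @param r variance ratio `sigma_random^2 / sigma_cat^2`.
#' @return `kalman_gain_sequence()`: numeric vector of gains `kappa_1..n`
#'   (the gain applied at each successive observation of one category;
#'   `kappa_1 = 0` since the first sample initializes the estimate).
#' @export
kalman_gain_sequence <- function(n_obs, r) {
  stopifnot(n_obs >= 1, r > 0)
  kappa <- numeric(n_obs)
  v <- 0
  kappa[1] <- 0
  if (n_obs > 1) {
    for (i in 2:n_obs) {
      v <- (1 - kappa[i - 1]) * v + r
      kappa[i] <- v / (v + 1)
    }
  }
  kappa
}

#' @rdname kalman_gain_sequence
#' @export
kalman_asymptotic_gain <- function(r) {
  stopifnot(all(r > 0))
  (-r + sqrt(r^2 + 4 * r)) / 2
}
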