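# Deterministic reconstruction of a model's criterion trajectory from a
# logged session. Given the stimulus sequence, the feedback-category labels
# and (for the delta rule) the logged correctness, every model's criterion
# on every trial is a deterministic function of the parameters, so the
# trial-wise likelihood reduces to probit (covert) or Gaussian (overt)
# terms around this trajectory.
#
# Recursions run on the unwrapped (continuous) stimulus series and results
# are wrapped at the end; with category SD 10 deg and walk steps of 5 deg,
# consecutive differences never approach the 90 deg ambiguity limit, so
# this matches the shortest-arc updates used by the simulator exactly.

# per-trial "estimate available before trial t" from per-occurrence
# estimate sequence est (length = #occurrences of the category)
estimate_before_trial <- function(est, is_cat) {
  n <- length(is_cat)
  occ_before <- c(0L, cumsum(is_cat))[seq_len(n)]
  ifelse(occ_before == 0L, NA_real_, est[pmax(occ_before, 1L)])
}

ewma_filter <- function(x, alpha) {
  if (length(x) == 0) return(numeric(0))
  if (alpha == 1) return(x)
  as.numeric(stats::filter(alpha * x, 1 - alpha, "recursive", init = x[1]))
}

running_mean_filter <- function(x) {
  if (length(x) == 0) return(numeric(0))
  cumsum(x) / seq_along(x)
}

kalman_filter_estimates <- function(x, r) {
  m <- length(x)
  if (m == 0) return(numeric(0))
  kappa <- kalman_gain_sequence(m, r)
  e <- numeric(m)
  e[1] <- x[1]
  if (m > 1) for (k in 2:m) e[k] <- e[k - 1] + kappa[k] * (x[k] - e[k - 1])
  e
}

#' Reconstruct a model's criterion trajectory from a session log
#'
#' Replays the learning rule over a logged session and returns the internal
#' criterion the model holds on each trial (the criterion applied to that
#' trial's stimulus). Mean-based models return `NA` on covert warm-up trials
#' (before both categories have been seen); for the overt task the warm-up
#' criterion is the single known sample, or 0 if none, matching the
#' simulator. The delta rule consumes the logged feedback, so its trajectory
#' is deterministic given `beta`.
#'
#' @param model_id an id from [model_registry()].
#' @param params named list with the parameters the rule needs (`alpha`,
#'   `beta`, `r`, `sigma_cat`).
#' @param session a session tibble from [simulate_covert_session()] or
#'   [simulate_overt_session()] (columns `stimulus_deg`, `true_category`,
#'   `correct`; overt also `criterion_deg`).
#' @param task `"covert"` or `"overt"`.
#' @param z_init delta-rule initial criterion; default 0 for covert and the
#'   first logged setting for overt.
#' @param ideal_n_mu mean-grid resolution for the ideal observer.
#' @return Numeric vector of criterion orientations, one per trial.
#' @export
criterion_trajectory <- function(model_id, params, session,
                                 task = c("covert", "overt"),
                                 z_init = NULL, ideal_n_mu = 61) {
  assert_model_id(model_id)
  task <- match.arg(task)
  n <- nrow(session)
  s <- unwrap_orientation(session$stimulus_deg)
  is_A <- session$true_category == "A"

  if (model_id == "delta_rule") {
    if (is.null(z_init)) {
      z_init <- if (task == "overt") session$criterion_deg[1] else 0
    }
    wrong <- !session$correct
    sw <- s[wrong]
    beta <- params$beta
    u <- if (beta == 0) rep(z_init, length(sw)) else
      as.numeric(stats::filter(beta * sw, 1 - beta, "recursive",
                               init = z_init))
    upd_before <- c(0L, cumsum(wrong))[seq_len(n)]
    z <- ifelse(upd_before == 0L, z_init, c(z_init, u)[upd_before + 1L])
    return(wrap_orientation(z))
  }

  if (model_id == "ideal_bayes") {
    z <- ideal_trajectory(s, is_A, sigma_cat = params$sigma_cat,
                          n_mu = ideal_n_mu)
    if (task == "overt") z <- fill_overt_warmup(z, s, is_A)
  } else {
    est_fun <- switch(model_id,
      bayes_selection = function(x) running_mean_filter(x),
      ewma = function(x) ewma_filter(x, params$alpha),
      kalman = function(x) kalman_filter_estimates(x, params$r),
      limited_memory = function(x) x
    )
    mu_A <- estimate_before_trial(est_fun(s[is_A]), is_A)
    mu_B <- estimate_before_trial(est_fun(s[!is_A]), !is_A)
    z <- (mu_A + mu_B) / 2
    if (task == "overt") {
      z <- ifelse(is.na(z),
                  ifelse(!is.na(mu_A), mu_A, ifelse(!is.na(mu_B), mu_B, 0)),
                  z)
    }
  }
  wrap_orientation(z)
}

# overt warm-up rule on a trajectory with NA entries: the running mean of
# the one category seen so far, or 0 before any sample has been seen
# (matches the simulator's warm-up behavior for the Bayesian models)
fill_overt_warmup <- function(z, s, is_A) {
  muA <- estimate_before_trial(running_mean_filter(s[is_A]), is_A)
  muB <- estimate_before_trial(running_mean_filter(s[!is_A]), !is_A)
  warm <- is.na(z)
  z[warm] <- ifelse(!is.na(muA[warm]), muA[warm],
                    ifelse(!is.na(muB[warm]), muB[warm], 0))
  z
}

# ideal-observer criterion per trial from incrementally grown sufficient
# statistics; NA until both categories observed. Operates on the unwrapped
# series (the quadrature is linear).
ideal_trajectory <- function(s, is_A, sigma_cat = NULL, n_mu = 61,
                             n_sigma = 31) {
  n <- length(s)
  z <- rep(NA_real_, n)
  st <- new_criterion_state("ideal_bayes")
  params <- list(sigma_cat = sigma_cat)
  for (t in seq_len(n)) {
    if (st$stats_A$n >= 1 && st$stats_B$n >= 1) {
      z[t] <- ideal_criterion(st, params, n_mu = n_mu, n_sigma = n_sigma)
    }
    st <- running_mean_update(st, s[t], if (is_A[t]) "A" else "B")
  }
  z
}

# Cache of ideal-observer trajectories over a log-spaced grid of category
# SDs; the likelihood interpolates the per-trial criterion linearly in
# log(sigma_cat). Used to make MCMC over the ideal model tractable.
ideal_trajectory_cache <- function(session, sigma_grid = exp(seq(log(2), log(40),
                                                                 length.out = 9)),
                                   n_mu = 61) {
  s <- unwrap_orientation(session$stimulus_deg)
  is_A <- session$true_category == "A"
  mat <- vapply(sigma_grid,
                function(sg) ideal_trajectory(s, is_A, sigma_cat = sg,
                                              n_mu = n_mu),
                numeric(length(s)))
  list(sigma_grid = sigma_grid, log_sigma = log(sigma_grid), z = mat)
}

ideal_trajectory_interpolate <- function(cache, sigma_cat) {
  ls <- log(sigma_cat)
  g <- cache$log_sigma
  if (ls <= g[1]) return(cache$z[, 1])
  K <- length(g)
  if (ls >= g[K]) return(cache$z[, K])
  j <- findInterval(ls, g)
  w <- (ls - g[j]) / (g[j + 1] - g[j])
  (1 - w) * cache$z[, j] + w * cache$z[, j + 1]
}
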