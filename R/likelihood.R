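# Trial-wise likelihoods and priors for every (model, task) pair.

param_info <- function(name) {
  switch(name,
    sigma_v = ,
    sigma_a = ,
    sigma_cat = list(lower = 0.5, upper = 60, prior = "jeffreys",
                     transform = "log"),
    alpha = ,
    beta = list(lower = 0, upper = 1, prior = "flat", transform = "logit"),
    r = list(lower = 0.01, upper = 100, prior = "flat", transform = "log"),
    stop("unknown parameter: ", name, call. = FALSE)
  )
}

#' Free parameters of a (model, task) fit
#'
#' Covert fits have the sensory noise SD `sigma_v` free plus the model's
#' learning parameter; overt fits have the adjustment noise SD `sigma_a`
#' free instead (sensory noise does not enter the overt likelihood, since
#' the learning signal is the presented stimulus).
#'
#' @param model_id an id from [model_registry()].
#' @param task `"covert"` or `"overt"`.
#' @return Character vector of free parameter names.
#' @export
free_parameters <- function(model_id, task = c("covert", "overt")) {
  assert_model_id(model_id)
  task <- match.arg(task)
  reg <- model_registry()
  row <- reg[reg$model_id == model_id, ]
  if (task == "covert") row$covert_free[[1]] else row$overt_free[[1]]
}

#' Log-likelihood of a covert-criterion session
#'
#' The model's criterion trajectory is reconstructed deterministically from
#' the logged feedback history; each trial then contributes the probit
#' probability of the logged response given the criterion, stimulus, and
#' sensory noise `params$sigma_v`. Warm-up trials (criterion undefined)
#' contribute log(1/2) (unbiased guessing).
#'
#' @param model_id an id from [model_registry()].
#' @param params named list of parameter values (must include `sigma_v` and
#'   the model's learning parameter).
#' @param session a covert session tibble.
#' @param cache optional precomputed ideal-observer trajectory cache.
#' @return Scalar log-likelihood (`-Inf` if non-finite terms arise).
#' @export
loglik_covert <- function(model_id, params, session, cache = NULL) {
  z <- session_trajectory(model_id, params, session, "covert", cache)
  d <- arc_diff(z, session$stimulus_deg) / params$sigma_v
  resp_A <- session$response == "A"
  lp <- ifelse(resp_A, stats::pnorm(d, log.p = TRUE),
               stats::pnorm(-d, log.p = TRUE))
  lp[is.na(z)] <- log(0.5)
  ll <- sum(lp)
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Log-likelihood of an overt-criterion session
#'
#' Gaussian log-density of the logged settings around the model's internal
#' criterion trajectory, with SD `params$sigma_a`.
#'
#' @inheritParams loglik_covert
#' @param session an overt session tibble (`criterion_deg` holds settings).
#' @return Scalar log-likelihood.
#' @export
loglik_overt <- function(model_id, params, session, cache = NULL) {
  theta_c <- session_trajectory(model_id, params, session, "overt", cache)
  resid <- arc_diff(session$criterion_deg, theta_c)
  ll <- sum(stats::dnorm(resid, 0, params$sigma_a, log = TRUE))
  if (!is.finite(ll)) return(-Inf)
  ll
}

session_trajectory <- function(model_id, params, session, task, cache = NULL) {
  if (model_id == "ideal_bayes" && !is.null(cache)) {
    z <- ideal_trajectory_interpolate(cache, params$sigma_cat)
    if (task == "overt") {
      z <- fill_overt_warmup(z, unwrap_orientation(session$stimulus_deg),
                             session$true_category == "A")
    }
    return(wrap_orientation(z))
  }
  criterion_trajectory(model_id, params, session, task)
}

#' Log-prior over observer parameters
#'
#' Jeffreys priors (density proportional to 1/sigma on a bounded support
#' \eqn{[0.5, 60]} degrees) for all SD parameters and flat priors on their
#' ranges for the learning parameters (`alpha`, `beta` on (0,1); the Kalman
#' variance ratio `r` on (0.01, 100]).
#'
#' @param params named list of parameter values.
#' @param free character vector of the free parameter names to evaluate.
#' @return Scalar unnormalized log-prior; `-Inf` outside the support.
#' @export
log_prior <- function(params, free = names(params)) {
  lp <- 0
  for (nm in free) {
    info <- param_info(nm)
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v) || v <= info$lower || v > info$upper) {
      return(-Inf)
    }
    if (info$prior == "jeffreys") lp <- lp - log(v)
  }
  lp
}

# transformed-scale helpers: MCMC proposes on log / logit scales; the
# log-posterior on the transformed scale adds the Jacobian of the inverse
# transform so that the stated natural-scale priors are preserved
to_transformed <- function(value, info) {
  switch(info$transform,
    log = log(value),
    logit = stats::qlogis((value - info$lower) / (info$upper - info$lower))
  )
}

from_transformed <- function(theta, info) {
  switch(info$transform,
    log = exp(theta),
    logit = info$lower + (info$upper - info$lower) * stats::plogis(theta)
  )
}

log_jacobian <- function(theta, info) {
  switch(info$transform,
    log = theta,
    logit = {
      p <- stats::plogis(theta)
      log(info$upper - info$lower) + log(p) + log1p(-p)
    }
  )
}
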