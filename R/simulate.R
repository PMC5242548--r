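#' Experiment configuration for the categorization tasks
#'
#' Bundles the generative conditions of a covert- or overt-criterion block:
#' two Gaussian stimulus categories with equal SD whose means are either
#' static within the block or follow a shared Gaussian random walk, 600
#' trials per block, and observer noise levels. The category separation
#' defaults to the value giving d' = 1 against the combined category and
#' sensory noise, mirroring how task difficulty is equated per observer.
#'
#' @param mode `"static"` or `"dynamic"`.
#' @param n_trials trials per block (default 600).
#' @param sigma_category category SD in degrees (default 10).
#' @param delta_theta separation `mu_B - mu_A` in degrees; if `NULL`,
#'   computed as `d_prime * sqrt(sigma_category^2 + sigma_v^2)`.
#' @param d_prime target discriminability used when `delta_theta` is `NULL`.
#' @param sigma_random SD of the per-trial random-walk step in degrees
#'   (dynamic mode; default 5).
#' @param sigma_v sensory noise SD in degrees (default 6, the group mean of
#'   the discrimination estimates under static conditions).
#' @param sigma_a adjustment noise SD in degrees (default 7.2, the group
#'   mean matching-noise estimate).
#' @param mu_A_range interval the initial category-A mean is drawn from.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("static", "dynamic"), n_trials = 600,
                              sigma_category = 10, delta_theta = NULL,
                              d_prime = 1, sigma_random = 5,
                              sigma_v = 6, sigma_a = 7.2,
                              mu_A_range = c(-50, 50)) {
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1, sigma_category > 0, sigma_random >= 0,
            sigma_v >= 0, sigma_a >= 0, length(mu_A_range) == 2,
            mu_A_range[1] < mu_A_range[2])
  if (is.null(delta_theta)) {
    delta_theta <- d_prime * sqrt(sigma_category^2 + sigma_v^2)
  }
  if (delta_theta <= 0) stop("delta_theta must be positive", call. = FALSE)
  structure(list(mode = mode, n_trials = as.integer(n_trials),
                 sigma_category = sigma_category, delta_theta = delta_theta,
                 sigma_random = sigma_random, sigma_v = sigma_v,
                 sigma_a = sigma_a, mu_A_range = mu_A_range),
            class = "experiment_config")
}

#' Initialize the latent category state
#'
#' Draws the category-A mean uniformly from the configured range and places
#' the category-B mean `delta_theta` degrees counter-clockwise of it, so the
#' A mean is always clockwise of the B mean.
#'
#' @param config an [experiment_config()].
#' @param seed optional integer seed for reproducibility.
#' @return A list of class `category_state` with fields `mu_A`, `mu_B`,
#'   `sigma`, `delta_theta`, `trial_index`.
#' @export
init_categories <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu_A <- stats::runif(1, config$mu_A_range[1], config$mu_A_range[2])
  structure(list(mu_A = mu_A,
                 mu_B = wrap_orientation(mu_A + config$delta_theta),
                 sigma = config$sigma_category,
                 delta_theta = config$delta_theta,
                 trial_index = 1L),
            class = "category_state")
}

#' Advance the category means by one random-walk step
#'
#' A single shared increment `eps ~ N(0, sigma_random)` is added to both
#' means, so their separation is preserved exactly; the trial index is
#' incremented.
#'
#' @param state a `category_state`.
#' @param sigma_random step SD in degrees.
#' @param eps optional fixed increment (used when replaying a walk).
#' @return The stepped `category_state`.
#' @export
step_random_walk <- function(state, sigma_random, eps = NULL) {
  if (is.null(eps)) {
    eps <- if (sigma_random == 0) 0 else stats::rnorm(1, 0, sigma_random)
  }
  state$mu_A <- wrap_orientation(state$mu_A + eps)
  state$mu_B <- wrap_orientation(state$mu_A + state$delta_theta)
  state$trial_index <- state$trial_index + 1L
  state
}

#' Draw one stimulus from the current category state
#'
#' The trial's category is equally likely to be A or B; the stimulus
#' orientation is drawn from that category's Gaussian and the measurement
#' adds sensory noise. All orientations are wrapped to (-90, 90].
#'
#' @param state a `category_state`.
#' @param config an [experiment_config()] (supplies `sigma_v`).
#' @return A list with `true_category`, `stimulus_deg`, `measurement_deg`.
#' @export
sample_trial <- function(state, config) {
  cat_A <- stats::runif(1) < 0.5
  mu <- if (cat_A) state$mu_A else state$mu_B
  s <- wrap_orientation(stats::rnorm(1, mu, state$sigma))
  x <- wrap_orientation(stats::rnorm(1, s, config$sigma_v))
  list(true_category = if (cat_A) "A" else "B",
       stimulus_deg = s, measurement_deg = x)
}

# criterion the model proposes for the next trial, NA while undefined
propose_criterion <- function(state, params) {
  if (state$model_id == "delta_rule") return(state$z)
  if (state$model_id == "ideal_bayes") {
    if (state$stats_A$n >= 1 && state$stats_B$n >= 1) {
      return(ideal_criterion(state, params))
    }
    # fall through to warm-up on the mean estimates
  }
  if (!is.na(state$mu_A) && !is.na(state$mu_B)) return(midpoint_criterion(state))
  NA_real_
}

# warm-up criterion for the overt task: the single known sample, or 0
overt_warmup_criterion <- function(state) {
  if (!is.na(state$mu_A)) return(state$mu_A)
  if (!is.na(state$mu_B)) return(state$mu_B)
  0
}

# feedback-driven state update shared by both tasks; the learning signal is
# the presented stimulus orientation by default (see package vignette)
update_observer <- function(state, x, category, feedback_correct, params) {
  switch(state$model_id,
    ideal_bayes = ,
    bayes_selection = running_mean_update(state, x, category),
    ewma = ewma_update(state, x, category, params$alpha),
    kalman = kalman_update(state, x, category, params$r),
    delta_rule = delta_rule_update(state, x, feedback_correct, params$beta),
    limited_memory = limited_memory_update(state, x, category)
  )
}

check_model_mode <- function(model_id, mode) {
  ok <- if (mode == "dynamic") .dynamic_models else .static_models
  if (!model_id %in% ok) {
    stop("model '", model_id, "' is not supported in ", mode, " mode",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a covert-criterion session
#'
#' Runs the closed loop of the categorization task: on every trial the
#' observer model proposes a decision criterion, the response is category A
#' when the noisy measurement falls clockwise of it, feedback reveals the
#' true category, and the model state is updated with the trial's stimulus
#' and feedback. Before both categories have been observed, mean-based
#' models respond by an unbiased guess.
#'
#' @param model_id an id from [model_registry()].
#' @param params named list of observer parameters (`alpha`, `beta`, `r`,
#'   `sigma_cat` as the model requires; `sigma_v` is taken from the config).
#' @param config an [experiment_config()].
#' @param seed optional integer seed.
#' @param learn_from `"stimulus"` (default) updates the model with the
#'   presented orientation; `"measurement"` uses the noisy measurement.
#' @return A tibble with one row per trial: `trial`, `task`, `mode`,
#'   `true_category`, `stimulus_deg`, `measurement_deg`, `criterion_deg`
#'   (the model's internal criterion, `NA` during warm-up), `response`,
#'   `correct`, `mu_A`, `mu_B`.
#' @export
simulate_covert_session <- function(model_id, params, config, seed = NULL,
                                    learn_from = c("stimulus", "measurement")) {
  assert_model_id(model_id)
  check_model_mode(model_id, config$mode)
  learn_from <- match.arg(learn_from)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  cat_state <- init_categories(config)
  obs <- new_criterion_state(model_id)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    z <- propose_criterion(obs, params)
    tr <- sample_trial(cat_state, config)
    if (is.na(z)) {
      resp_A <- stats::runif(1) < 0.5
    } else {
      d <- arc_diff(z, tr$measurement_deg)
      resp_A <- if (d > 0) TRUE else if (d < 0) FALSE else stats::runif(1) < 0.5
    }
    correct <- resp_A == (tr$true_category == "A")
    sig <- if (learn_from == "stimulus") tr$stimulus_deg else tr$measurement_deg
    obs <- update_observer(obs, sig, tr$true_category, correct, params)
    out[[i]] <- tibble::tibble(
      trial = i, task = "covert", mode = config$mode,
      true_category = tr$true_category, stimulus_deg = tr$stimulus_deg,
      measurement_deg = tr$measurement_deg, criterion_deg = z,
      response = if (resp_A) "A" else "B", correct = correct,
      mu_A = cat_state$mu_A, mu_B = cat_state$mu_B
    )
    if (config$mode == "dynamic" && i < n) {
      cat_state <- step_random_walk(cat_state, config$sigma_random)
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate an overt-criterion session
#'
#' On every trial the observer model emits its internal criterion; the
#' logged setting adds Gaussian adjustment noise. A stimulus is then drawn
#' and feedback is positive when the stimulus is on the correct side of the
#' *logged* setting (category A clockwise of it, B counter-clockwise). The
#' model state is updated with the stimulus and feedback. Before both
#' categories have been observed, mean-based models set the criterion at the
#' single known sample (0 degrees if none).
#'
#' @inheritParams simulate_covert_session
#' @return A tibble as in [simulate_covert_session()] with `task = "overt"`;
#'   `criterion_deg` is the logged (noisy) setting, `theta_c_deg` the
#'   model's internal criterion, and `response` is `NA` (no categorization
#'   response is made).
#' @export
simulate_overt_session <- function(model_id, params, config, seed = NULL,
                                   learn_from = c("stimulus", "measurement")) {
  assert_model_id(model_id)
  check_model_mode(model_id, config$mode)
  learn_from <- match.arg(learn_from)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  cat_state <- init_categories(config)
  obs <- new_criterion_state(model_id)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    theta_c <- propose_criterion(obs, params)
    if (is.na(theta_c)) theta_c <- overt_warmup_criterion(obs)
    z <- if (config$sigma_a == 0) theta_c else
      wrap_orientation(theta_c + stats::rnorm(1, 0, config$sigma_a))
    tr <- sample_trial(cat_state, config)
    d <- arc_diff(z, tr$stimulus_deg)  # > 0: stimulus clockwise of setting
    correct <- if (tr$true_category == "A") d > 0 else d <= 0
    sig <- if (learn_from == "stimulus") tr$stimulus_deg else tr$measurement_deg
    obs <- update_observer(obs, sig, tr$true_category, correct, params)
    out[[i]] <- tibble::tibble(
      trial = i, task = "overt", mode = config$mode,
      true_category = tr$true_category, stimulus_deg = tr$stimulus_deg,
      measurement_deg = tr$measurement_deg, criterion_deg = z,
      theta_c_deg = theta_c, response = NA_character_, correct = correct,
      mu_A = cat_state$mu_A, mu_B = cat_state$mu_B
    )
    if (config$mode == "dynamic" && i < n) {
      cat_state <- step_random_walk(cat_state, config$sigma_random)
    }
  }
  dplyr::bind_rows(out)
}

#' Staircase configuration for the 2IFC discrimination task
#'
#' Four interleaved staircases (two 1-up-2-down, two 1-up-3-down) of 65
#' trials each, stepping over a log-spaced ladder of orientation differences
#' from 0.25 to 16 degrees.
#'
#' @param rules character vector of staircase rules.
#' @param trials_per_staircase trials per staircase (default 65).
#' @param levels log-spaced ladder of orientation differences in degrees.
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(rules = c("one_up_two_down", "one_up_two_down",
                                       "one_up_three_down", "one_up_three_down"),
                             trials_per_staircase = 65,
                             levels = exp(seq(log(0.25), log(16),
                                              length.out = 25))) {
  stopifnot(all(rules %in% c("one_up_two_down", "one_up_three_down")),
            trials_per_staircase >= 1, all(diff(levels) > 0), all(levels > 0))
  structure(list(rules = rules,
                 trials_per_staircase = as.integer(trials_per_staircase),
                 levels = levels),
            class = "staircase_config")
}

down_count <- function(rule) if (rule == "one_up_two_down") 2L else 3L

#' Simulate the 2IFC orientation-discrimination staircases
#'
#' Two ellipses are shown in sequence; the observer picks the more clockwise
#' one. The probability of a correct choice follows a cumulative normal in
#' the orientation difference with difference-SD `sigma_v * sqrt(2)` and a
#' lapse floor. Staircases move one ladder position down after the required
#' run of correct responses and one up after any error; the staircase run on
#' each trial is chosen uniformly at random among those not yet finished.
#'
#' @param sigma_v sensory noise SD in degrees (per interval).
#' @param staircase a [staircase_config()].
#' @param lapse lapse rate in \eqn{[0, 0.1]}.
#' @param seed optional integer seed.
#' @return A tibble with one row per trial: `trial`, `staircase`, `rule`,
#'   `delta_theta` (unsigned level), `signed_delta` (second minus first
#'   interval orientation), `choice_interval` (1 or 2), `correct`.
#' @export
simulate_discrimination_staircase <- function(sigma_v, staircase = staircase_config(),
                                              lapse = 0.02, seed = NULL) {
  stopifnot(sigma_v >= 0, lapse >= 0, lapse <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  n_sc <- length(staircase$rules)
  idx <- rep(length(staircase$levels), n_sc)  # start at the easiest level
  run <- rep(0L, n_sc)                        # consecutive-correct counter
  left <- rep(staircase$trials_per_staircase, n_sc)
  sd2 <- sigma_v * sqrt(2)
  n_total <- sum(left)
  sc_v <- integer(n_total); dt_v <- numeric(n_total)
  sd_v <- numeric(n_total); ch_v <- integer(n_total); co_v <- logical(n_total)
  t <- 0L
  while (any(left > 0)) {
    open <- which(left > 0)
    sc <- if (length(open) == 1L) open else sample(open, 1)
    t <- t + 1L
    dtheta <- staircase$levels[idx[sc]]
    cw_second <- stats::runif(1) < 0.5  # is the second interval more clockwise?
    signed_delta <- if (cw_second) -dtheta else dtheta
    # probability of choosing interval 1 as the more clockwise one
    p1 <- if (sd2 == 0) as.numeric(signed_delta > 0) + 0.5 * (signed_delta == 0)
          else stats::pnorm(signed_delta / sd2)
    p1 <- lapse / 2 + (1 - lapse) * p1
    choice1 <- stats::runif(1) < p1
    correct <- (choice1 && signed_delta > 0) || (!choice1 && signed_delta < 0)
    if (correct) {
      run[sc] <- run[sc] + 1L
      if (run[sc] >= down_count(staircase$rules[sc])) {
        idx[sc] <- max(idx[sc] - 1L, 1L)
        run[sc] <- 0L
      }
    } else {
      idx[sc] <- min(idx[sc] + 1L, length(staircase$levels))
      run[sc] <- 0L
    }
    left[sc] <- left[sc] - 1L
    sc_v[t] <- sc; dt_v[t] <- dtheta; sd_v[t] <- signed_delta
    ch_v[t] <- if (choice1) 1L else 2L; co_v[t] <- correct
  }
  rules_v <- staircase$rules[sc_v]
  tibble::tibble(trial = seq_len(n_total), staircase = sc_v,
                 rule = rules_v, delta_theta = dt_v,
                 signed_delta = sd_v, choice_interval = ch_v, correct = co_v)
}

#' Simulate an orientation-matching session
#'
#' Targets are uniform on (-90, 90]; settings add Gaussian adjustment noise
#' and are wrapped.
#'
#' @param sigma_a adjustment noise SD in degrees.
#' @param n_trials number of trials (default 260).
#' @param seed optional integer seed.
#' @return A tibble with `trial`, `target_deg`, `setting_deg`.
#' @export
simulate_matching_session <- function(sigma_a, n_trials = 260, seed = NULL) {
  stopifnot(sigma_a >= 0, n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  target <- wrap_orientation(stats::runif(n_trials, -90, 90))
  setting <- if (sigma_a == 0) target else
    wrap_orientation(target + stats::rnorm(n_trials, 0, sigma_a))
  tibble::tibble(trial = seq_len(n_trials), target_deg = target,
                 setting_deg = setting)
}
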