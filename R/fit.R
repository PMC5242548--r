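#' Fit a criterion-learning model to one session by MCMC
#'
#' Samples the posterior over the model's free parameters (see
#' [free_parameters()]) with the adaptive Metropolis-within-Gibbs sampler,
#' then computes split-chain R-hat, DIC, posterior summaries and the MAP
#' estimate. The ideal Bayesian observer is handled through a precomputed
#' trajectory cache over a grid of category SDs, which makes its otherwise
#' quadrature-heavy likelihood tractable.
#'
#' @param session a session tibble from [simulate_covert_session()],
#'   [simulate_overt_session()] or [read_session_csv()].
#' @param model_id an id from [model_registry()].
#' @param task `"covert"` or `"overt"`; defaults to the session's task
#'   column.
#' @param fixed named list of parameters to hold fixed.
#' @param plan a [chain_plan()].
#' @param seed integer seed controlling chain initialization and proposals.
#' @return An object of class `criterion_fit` with elements `samples` (the
#'   `posterior_samples`), `map`, `posterior_mean`, `posterior_sd`, `rhat`,
#'   `ess`, `dic`, `p_d`, `mean_deviance`, `model_id`, `task`, `n_trials`.
#' @examples
#' \donttest{
#' cfg <- experiment_config("static", n_trials = 200)
#' sess <- simulate_covert_session("ewma", list(alpha = 0.3), cfg, seed = 7)
#' fit <- fit_observer_model(sess, "ewma",
#'                           plan = chain_plan(2, 100, 100, 300), seed = 7)
#' glance(fit)
#' }
#' @export
fit_observer_model <- function(session, model_id, task = NULL,
                               fixed = list(), plan = chain_plan(),
                               seed = 1) {
  assert_model_id(model_id)
  if (is.null(task)) task <- session$task[1]
  task <- match.arg(task, c("covert", "overt"))
  mode <- if ("mode" %in% names(session)) session$mode[1] else "static"
  check_model_mode(model_id, mode)
  cache <- NULL
  if (model_id == "ideal_bayes" &&
      !"sigma_cat" %in% names(fixed)) {
    cache <- ideal_trajectory_cache(session)
  }
  samples <- run_mcmc(model_id, session, task, fixed = fixed, plan = plan,
                      seed = seed, cache = cache)
  rhat <- gelman_rubin(samples)
  ic <- dic(samples)
  post_mean <- apply(samples$draws, 3, mean)
  post_sd <- apply(samples$draws, 3, stats::sd)
  names(post_mean) <- names(post_sd) <- samples$free
  structure(list(samples = samples, map = map_estimate(samples),
                 posterior_mean = post_mean, posterior_sd = post_sd,
                 rhat = rhat, ess = effective_size(samples),
                 dic = ic$dic, p_d = ic$p_d,
                 mean_deviance = ic$mean_deviance,
                 model_id = model_id, task = task, mode = mode,
                 n_trials = nrow(session), seed = seed, plan = plan),
            class = "criterion_fit")
}

#' @export
print.criterion_fit <- function(x, ...) {
  cat("<criterion_fit> model:", x$model_id, " task:", x$task,
      " mode:", x$mode, "\n")
  cat(sprintf("  %d trials, %d chains x %d draws\n", x$n_trials,
              x$plan$n_chains, x$plan$n_samples))
  cat(sprintf("  DIC %.1f (p_D %.2f), max R-hat %.3f\n",
              x$dic, x$p_d, max(x$rhat, na.rm = TRUE)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted criterion-learning model
#'
#' @param x a `criterion_fit`.
#' @param ... unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`
#'   (MAP), `post_mean`, `post_sd`, `rhat`, `ess`.
#' @export
tidy.criterion_fit <- function(x, ...) {
  tibble::tibble(term = x$samples$free,
                 estimate = unlist(x$map[x$samples$free]),
                 post_mean = unname(x$posterior_mean),
                 post_sd = unname(x$posterior_sd),
                 rhat = unname(x$rhat),
                 ess = unname(x$ess))
}

#' @rdname tidy.criterion_fit
#' @return `glance()` returns a one-row tibble with `model_id`, `task`,
#'   `dic`, `p_d`, `mean_deviance`, `max_rhat`, `n_trials`.
#' @export
glance.criterion_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, task = x$task, mode = x$mode,
                 dic = x$dic, p_d = x$p_d,
                 mean_deviance = x$mean_deviance,
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 n_trials = x$n_trials)
}

#' Trace plot of the posterior draws
#'
#' @param object a `criterion_fit`.
#' @param ... unused.
#' @return A ggplot object with one facet per parameter.
#' @export
autoplot.criterion_fit <- function(object, ...) {
  d <- object$samples$draws
  df <- purrr::map_dfr(seq_along(object$samples$free), function(i) {
    tibble::tibble(
      parameter = object$samples$free[i],
      chain = factor(rep(seq_len(dim(d)[2]), each = dim(d)[1])),
      iteration = rep(seq_len(dim(d)[1]), dim(d)[2]),
      value = as.vector(d[, , i])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   color = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "parameter value",
                  title = paste(object$model_id, object$task, "posterior traces"))
}
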