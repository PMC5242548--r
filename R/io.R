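#' Derive a per-stage child seed from a master seed
#'
#' One master seed expands deterministically into per-stage, per-subject
#' seeds by a fixed counter scheme, so independent pipeline stages stay
#' reproducible when run in isolation. All derived seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage counter (0, 1, 2, ...).
#' @param subject subject counter (default 0).
#' @return Integer seed.
#' @export
child_seed <- function(seed, stage, subject = 0) {
  as.integer((as.double(seed) * 7919 + stage * 104729 + subject * 7907) %%
               2147483647)
}

#' Write / read a session trial log as CSV
#'
#' Plain RFC-4180 CSV, UTF-8, "." decimal, orientations in degrees with 4
#' decimals — one file per session.
#'
#' @param session a session tibble.
#' @param path file path.
#' @return `write_session_csv()` returns `path` invisibly;
#'   `read_session_csv()` the session tibble.
#' @export
write_session_csv <- function(session, path) {
  out <- session
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% "trial"
  out[num] <- lapply(out[num], round, digits = 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
  tibble::as_tibble(df)
}

#' Read / write an experiment configuration as JSON
#'
#' The JSON mirrors [experiment_config()] plus a mandatory `seed` and an
#' optional `n_subjects` and observer-model block (`model_id`, `params`).
#'
#' @param path JSON file path.
#' @return `read_config_json()` returns a list with `config` (an
#'   `experiment_config`), `seed`, `n_subjects`, `model_id`, `params`.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- "seed"
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  known <- c("mode", "n_trials", "sigma_category", "delta_theta", "d_prime",
             "sigma_random", "sigma_v", "sigma_a", "mu_A_range")
  cfg_args <- raw[intersect(names(raw), known)]
  cfg <- do.call(experiment_config, cfg_args)
  list(config = cfg, seed = as.integer(raw$seed),
       n_subjects = if (is.null(raw$n_subjects)) 1L else
         as.integer(raw$n_subjects),
       model_id = if (is.null(raw$model_id)) "ewma" else raw$model_id,
       params = if (is.null(raw$params)) list(alpha = 0.3) else
         as.list(raw$params))
}

#' @rdname read_config_json
#' @param config list as returned by [read_config_json()] (or any list of
#'   scalar settings).
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a batch of sessions to CSV files with a run manifest
#'
#' One CSV per (subject, task); a JSON manifest records the configuration,
#' the master seed, and every output path, so re-running with the same
#' manifest reproduces the files byte for byte.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param n_subjects number of simulated observers.
#' @param model_id generating observer model.
#' @param params generating parameters.
#' @param tasks tasks to simulate (default both).
#' @param seed master seed.
#' @return The manifest as a list (invisibly written to
#'   `manifest.json` in `out_dir`).
#' @export
simulate_to_dir <- function(config, out_dir, n_subjects = 1,
                            model_id = "ewma", params = list(alpha = 0.3),
                            tasks = c("covert", "overt"), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (subj in seq_len(n_subjects)) {
    for (task in tasks) {
      stage <- if (task == "covert") 1 else 2
      sess <- if (task == "covert") {
        simulate_covert_session(model_id, params, config,
                                seed = child_seed(seed, stage, subj))
      } else {
        simulate_overt_session(model_id, params, config,
                               seed = child_seed(seed, stage, subj))
      }
      fn <- file.path(out_dir, sprintf("subject%02d_%s_%s.csv", subj, task,
                                       config$mode))
      write_session_csv(sess, fn)
      files[[length(files) + 1]] <- list(subject = subj, task = task,
                                         path = fn)
    }
  }
  manifest <- list(seed = seed, n_subjects = n_subjects,
                   model_id = model_id, params = params,
                   config = unclass(config), files = files)
  write_config_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Serialize a fit to JSON
#'
#' MAP, posterior summaries, R-hat, effective sizes, DIC and chain metadata.
#'
#' @param fit a `criterion_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    model_id = fit$model_id, task = fit$task, mode = fit$mode,
    n_trials = fit$n_trials,
    map = fit$map,
    posterior = list(mean = as.list(fit$posterior_mean),
                     sd = as.list(fit$posterior_sd)),
    rhat = as.list(fit$rhat), ess = as.list(fit$ess),
    dic = fit$dic, p_d = fit$p_d, mean_deviance = fit$mean_deviance,
    chain_plan = fit$plan, seed = fit$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
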