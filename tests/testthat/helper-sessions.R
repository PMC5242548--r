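# Shared fixtures, generated in code. Sessions are memoised per test run so
# expensive simulations are built once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

static_config <- function(n_trials = 600, sigma_v = 6, ...) {
  experiment_config("static", n_trials = n_trials, sigma_v = sigma_v, ...)
}

dynamic_config <- function(n_trials = 600, sigma_v = 6, ...) {
  experiment_config("dynamic", n_trials = n_trials, sigma_v = sigma_v, ...)
}

covert_ewma_session <- function(seed = 101, alpha = 0.3, ...) {
  fixture(paste0("covert_ewma_", seed, "_", alpha), {
    simulate_covert_session("ewma", list(alpha = alpha),
                            static_config(...), seed = seed)
  })
}

overt_lm_session <- function(seed = 202, sigma_a = 0.5) {
  fixture(paste0("overt_lm_", seed, "_", sigma_a), {
    simulate_overt_session("limited_memory", list(),
                           static_config(sigma_a = sigma_a), seed = seed)
  })
}

# a small ideal-observer state with fixed histories
ideal_state_with <- function(xa, xb) {
  st <- new_criterion_state("ideal_bayes")
  for (x in xa) st <- running_mean_update(st, x, "A")
  for (x in xb) st <- running_mean_update(st, x, "B")
  st
}
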