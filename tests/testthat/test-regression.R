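test_that("the lagged design has the stated shape and bookkeeping", {
  sess <- covert_ewma_session()
  d <- build_lagged_design(sess)
  # warm-up loss: with balanced categories about 20 leading trials lack a
  # 9-deep history in one of the categories
  expect_gt(nrow(d), 560)
  expect_lt(nrow(d), 596)
  expect_true(all(paste0("A_lag", 1:9) %in% names(d)))
  expect_true(all(paste0("B_lag", 1:9) %in% names(d)))
  expect_true("stim0" %in% names(d))  # covert includes the current stimulus

  ov <- overt_lm_session()
  dov <- build_lagged_design(ov)
  expect_false("stim0" %in% names(dov))
  expect_type(dov$response, "double")

  # on category-A trials the A window slides by one, so a given A ellipse
  # passes through each A-lag column exactly once
  un <- unwrap_orientation(sess$stimulus_deg)
  a_trials <- which(sess$true_category == "A")
  probe <- un[a_trials[100]] - mean(un)
  dA <- d[d$trial %in% a_trials, ]
  hits <- vapply(paste0("A_lag", 1:9), function(cl) sum(dA[[cl]] == probe),
                 numeric(1))
  expect_equal(unname(hits), rep(1, 9))

  expect_error(build_lagged_design(sess[1:60, ]), "short")
  # smaller histories shrink the design accordingly
  d5 <- build_lagged_design(sess, n_lags = 5)
  expect_equal(sum(grepl("lag", names(d5))), 10)
})

test_that("logistic recovery of known generative weights at n = 5000", {
  sess <- fixture("big_covert", {
    simulate_covert_session("ewma", list(alpha = 0.3),
                            static_config(n_trials = 5000), seed = 131)
  })
  d <- build_lagged_design(sess)
  truth <- c(stim0 = -0.25, A_lag1 = 0.12, B_lag1 = 0.12)
  set.seed(132)
  eta <- 0.1 + truth["stim0"] * d$stim0 +
    truth["A_lag1"] * d$A_lag1 + truth["B_lag1"] * d$B_lag1
  d$response <- factor(ifelse(runif(nrow(d)) < plogis(eta), "A", "B"),
                       levels = c("B", "A"))
  fit <- fit_lagged_logistic(d)
  for (nm in names(truth)) {
    row <- fit[fit$term == nm, ]
    expect_lt(abs(row$estimate - truth[nm]), 2 * row$std_error)
  }
  expect_false(attr(fit, "separation"))
})

test_that("all-identical responses are rejected", {
  sess <- covert_ewma_session()
  d <- build_lagged_design(sess)
  d$response <- factor(rep("A", nrow(d)), levels = c("B", "A"))
  expect_error(fit_lagged_logistic(d), "identical")
})

test_that("limited-memory overt settings load on lag one at weight one half", {
  ov <- fixture("overt_lm_reg", {
    simulate_overt_session("limited_memory", list(),
                           static_config(n_trials = 2000, sigma_a = 0.5),
                           seed = 133)
  })
  d <- build_lagged_design(ov)
  fit <- fit_lagged_linear(d)
  lag1 <- unname(fit$estimate[fit$term %in% c("A_lag1", "B_lag1")])
  expect_equal(lag1, c(0.5, 0.5), tolerance = 0.05)
  others <- fit$estimate[grepl("lag[2-9]", fit$term)]
  expect_lt(max(abs(others)), 0.05)
})

test_that("pure-noise settings yield null weights", {
  set.seed(134)
  ov <- overt_lm_session()
  d <- build_lagged_design(ov)
  d$response <- rnorm(nrow(d), 0, 10)
  fit <- fit_lagged_linear(d)
  lags <- fit[grepl("lag", fit$term), ]
  cover <- mean(abs(lags$estimate) < 2 * lags$std_error)
  expect_gte(cover, 0.85)
})

test_that("group-level beta tests flag exactly the non-null lags", {
  betas0 <- tidyr::expand_grid(subject = 1:10, term = paste0("A_lag", 1:3))
  betas0$estimate <- 0
  res0 <- group_beta_tests(betas0)
  expect_false(any(res0$significant))
  set.seed(135)
  betas1 <- betas0
  betas1$estimate <- ifelse(betas1$term == "A_lag1",
                            rnorm(nrow(betas1), 1, 0.1),
                            rnorm(nrow(betas1), 0, 0.1))
  res1 <- group_beta_tests(betas1)
  expect_true(res1$significant[res1$term == "A_lag1"])
  expect_true(all(res1$p_value >= 0 & res1$p_value <= 1))
})

test_that("cross-correlation recovers constructed shifts exactly", {
  set.seed(136)
  omni <- cumsum(rnorm(600, 0, 3))
  shifted <- dplyr::lag(omni, 3, default = omni[1])
  res <- cross_correlation_lag(shifted, omni, max_lag = 20)
  expect_identical(res$lag, 3L)
  res0 <- cross_correlation_lag(omni, omni)
  expect_identical(res0$lag, 0L)
  expect_equal(res0$correlation, 1)
  expect_error(cross_correlation_lag(rep(1, 100), rnorm(100)), "constant")
})

test_that("EWMA tracking in dynamic mode lags the walk by a few trials", {
  dyn <- dynamic_config(sigma_a = 2)
  ov <- simulate_overt_session("ewma", list(alpha = 0.4), dyn, seed = 137)
  res <- cross_correlation_lag(ov$criterion_deg, omniscient_criterion(ov))
  expect_gte(res$lag, 1)
  expect_lte(res$lag, 6)
})

test_that("RMSE from the optimal criterion behaves as a proper deviation measure", {
  ov <- overt_lm_session()
  opt <- omniscient_criterion(ov)
  expect_equal(rmse_from_optimal(opt, ov), 0)
  set.seed(138)
  noisy <- wrap_orientation(opt + rnorm(length(opt), 0, 5))
  expect_equal(rmse_from_optimal(noisy, ov), 5, tolerance = 0.1 * 5)
  # translation invariance (away from the wrap)
  expect_equal(rmse_from_optimal(noisy + 3, opt + 3),
               rmse_from_optimal(noisy, opt), tolerance = 1e-10)
})
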