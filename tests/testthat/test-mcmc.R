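test_that("the sampler matches the conjugate posterior for a scale parameter", {
  # overt limited-memory fit: the criterion trajectory is parameter-free, so
  # the only free parameter sigma_a has the analytic posterior
  # sigma^2 ~ Inv-Gamma(n/2, S/2) under the Jeffreys prior (truncation at
  # [0.5, 60] is immaterial here)
  cfg <- static_config(sigma_a = 4)
  ov <- simulate_overt_session("limited_memory", list(), cfg, seed = 111)
  theta_c <- criterion_trajectory("limited_memory", list(), ov, "overt")
  r <- arc_diff(ov$criterion_deg, theta_c)
  n <- length(r); S <- sum(r^2)
  # closed-form moments of sigma = sqrt(phi), phi ~ InvGamma(n/2, S/2)
  e_sigma <- sqrt(S / 2) * exp(lgamma((n - 1) / 2) - lgamma(n / 2))
  e_sigma2 <- (S / 2) / (n / 2 - 1)
  sd_sigma <- sqrt(e_sigma2 - e_sigma^2)
  fit <- run_mcmc("limited_memory", ov, "overt",
                  plan = chain_plan(3, 300, 300, 1500), seed = 11)
  draws <- as.vector(fit$draws[, , "sigma_a"])
  expect_equal(mean(draws), e_sigma, tolerance = 4 * sd_sigma / sqrt(200))
  expect_equal(sd(draws), sd_sigma, tolerance = 0.15 * sd_sigma)
  # a single scale parameter contributes about one effective parameter
  ic <- dic(fit)
  expect_equal(ic$p_d, 1, tolerance = 0.5)
  expect_true(all(gelman_rubin(fit) < 1.1))
})

test_that("chains are reproducible under a fixed seed", {
  ov <- overt_lm_session()
  plan <- chain_plan(2, 100, 100, 200)
  f1 <- run_mcmc("limited_memory", ov, "overt", plan = plan, seed = 3)
  f2 <- run_mcmc("limited_memory", ov, "overt", plan = plan, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("split-chain R-hat flags divergence and passes agreement", {
  set.seed(112)
  agree <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(gelman_rubin(agree), 1.05)
  diverged <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(diverged), 1.5)
  # duplicated half-chains: between-variance vanishes, R-hat ~ 1
  seq1 <- rnorm(500)
  dup <- cbind(c(seq1, seq1), c(seq1, seq1))
  expect_equal(gelman_rubin(dup), 1, tolerance = 2e-3)
  # zero-variance chains are undefined
  expect_true(is.na(gelman_rubin(cbind(rep(1, 100), rep(1, 100)))))
})

test_that("DIC reduces to the plain deviance with no effective parameters", {
  d0 <- 123.4
  fake <- structure(list(
    draws = array(7, c(50, 2, 1), dimnames = list(NULL, NULL, "sigma_a")),
    deviance = matrix(d0, 50, 2),
    lp = matrix(0, 50, 2),
    free = "sigma_a",
    log_post = function(theta) c(0, -d0 / 2)
  ), class = "posterior_samples")
  ic <- dic(fake)
  expect_equal(ic$p_d, 0)
  expect_equal(ic$dic, d0)
})

test_that("DIC is invariant to chain concatenation order", {
  ov <- overt_lm_session()
  fit <- run_mcmc("limited_memory", ov, "overt",
                  plan = chain_plan(2, 100, 100, 300), seed = 5)
  swapped <- fit
  swapped$draws <- fit$draws[, 2:1, , drop = FALSE]
  swapped$deviance <- fit$deviance[, 2:1]
  expect_equal(dic(fit)$dic, dic(swapped)$dic, tolerance = 1e-10)
})

test_that("the MAP estimate dominates every sampled draw", {
  ov <- overt_lm_session()
  fit <- run_mcmc("limited_memory", ov, "overt",
                  plan = chain_plan(2, 100, 100, 300), seed = 6)
  map <- map_estimate(fit)
  theta_map <- critlearn:::to_transformed(map$sigma_a,
                                          critlearn:::param_info("sigma_a"))
  expect_gte(fit$log_post(theta_map)[1] + 1e-8, max(fit$lp))
})

test_that("a short covert fit recovers the generating EWMA weight roughly", {
  sess <- covert_ewma_session()
  fit <- fit_observer_model(sess, "ewma",
                            plan = chain_plan(2, 200, 200, 600), seed = 8)
  expect_gt(fit$map$alpha, 0.15)
  expect_lt(fit$map$alpha, 0.45)
  expect_equal(fit$map$sigma_v, 6, tolerance = 0.4 * 6)
  td <- tidy(fit)
  expect_setequal(td$term, c("sigma_v", "alpha"))
  expect_true(all(c("dic", "p_d", "max_rhat") %in% names(glance(fit))))
})
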