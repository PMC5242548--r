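test_that("running-mean recursion reproduces the batch mean exactly", {
  st <- new_criterion_state("bayes_selection")
  st <- running_mean_update(st, 10, "A")
  st <- running_mean_update(st, 20, "A")
  expect_equal(st$mu_A, 15)
  # recursion == batch mean to machine precision over 600 samples
  set.seed(31)
  xs <- rnorm(600, -5, 10)
  st <- new_criterion_state("bayes_selection")
  for (x in xs) st <- running_mean_update(st, x, "A")
  expect_equal(st$mu_A, mean(xs), tolerance = 1e-12)
  # order invariance
  st2 <- new_criterion_state("bayes_selection")
  for (x in sample(xs)) st2 <- running_mean_update(st2, x, "A")
  expect_equal(st2$mu_A, st$mu_A, tolerance = 1e-10)
})

test_that("EWMA updates only the presented category and matches its weighted-sum form", {
  st <- new_criterion_state("ewma")
  st <- ewma_update(st, 0, "A", 0.5)   # initializes at first sample
  st <- ewma_update(st, 10, "A", 0.5)
  expect_equal(st$mu_A, 5)
  expect_true(is.na(st$mu_B))
  # unrolled estimate equals the normalized geometric-weight sum (oracle)
  set.seed(32)
  xs <- rnorm(50, 8, 10)
  alpha <- 0.27
  st <- new_criterion_state("ewma")
  for (x in xs) st <- ewma_update(st, x, "A", alpha)
  n <- length(xs)
  w <- c((1 - alpha)^(n - 1), alpha * (1 - alpha)^((n - 2):0))
  expect_equal(st$mu_A, sum(w * xs), tolerance = 1e-10)
})

test_that("EWMA with alpha = 1 is exactly the limited-memory rule", {
  set.seed(33)
  xs <- rnorm(40, 0, 20)
  cats <- sample(c("A", "B"), 40, replace = TRUE)
  s1 <- new_criterion_state("ewma")
  s2 <- new_criterion_state("limited_memory")
  for (i in seq_along(xs)) {
    s1 <- ewma_update(s1, xs[i], cats[i], 1)
    s2 <- limited_memory_update(s2, xs[i], cats[i])
    expect_identical(s1$mu_A, s2$mu_A)
    expect_identical(s1$mu_B, s2$mu_B)
  }
})

test_that("small-alpha EWMA approaches the running mean", {
  set.seed(34)
  xs <- rnorm(5000, 3, 10)
  s1 <- new_criterion_state("ewma")
  for (x in xs) s1 <- ewma_update(s1, x, "A", 0.001)
  expect_lt(abs(s1$mu_A - mean(xs)), 0.5)
})

test_that("Kalman gain follows the stated recursion and fixed point", {
  # second observation with sigma_random = 5, sigma_cat = 10: kappa = 0.2
  st <- new_criterion_state("kalman")
  st <- kalman_update(st, 0, "A", r = 25 / 100)
  st <- kalman_update(st, 10, "A", r = 25 / 100)
  expect_equal(st$kappa_A, 0.2)
  expect_equal(st$mu_A, 2)
  # asymptote equals the positive root of kappa^2 + r kappa - r = 0
  for (r in c(0.1, 0.5, 1, 2, 10)) {
    kinf <- kalman_asymptotic_gain(r)
    expect_equal(kinf^2 + r * kinf - r, 0, tolerance = 1e-12)
    ks <- kalman_gain_sequence(50, r)
    expect_lt(abs(ks[50] - kinf), 1e-6)
  }
})

test_that("Kalman trajectories depend on the variance ratio only", {
  set.seed(35)
  xs <- rnorm(30, 0, 10)
  # same ratio from different absolute scales gives identical gains by
  # construction; check the update path at the ratio is scale-free
  e1 <- critlearn:::kalman_filter_estimates(xs, r = 25 / 100)
  e2 <- critlearn:::kalman_filter_estimates(xs, r = 2.5 / 10)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("delta rule moves only on errors", {
  st <- new_criterion_state("delta_rule")
  st1 <- delta_rule_update(st, 10, feedback_correct = TRUE, beta = 0.5)
  expect_equal(st1$z, 0)
  st2 <- delta_rule_update(st, 10, feedback_correct = FALSE, beta = 0.5)
  expect_equal(st2$z, 5)
  st3 <- delta_rule_update(st, 10, feedback_correct = FALSE, beta = 1)
  expect_equal(st3$z, 10)
})

test_that("limited memory keeps the last sample and sets the midpoint criterion", {
  st <- new_criterion_state("limited_memory")
  st <- limited_memory_update(st, -20, "A")
  st <- limited_memory_update(st, 4, "B")
  st <- limited_memory_update(st, 7, "A")
  expect_equal(st$mu_A, 7)
  expect_equal(midpoint_criterion(st), (7 + 4) / 2)
})

test_that("midpoint criterion is symmetric and errors during warm-up", {
  st <- new_criterion_state("ewma")
  st$mu_A <- -10; st$mu_B <- 10
  expect_equal(midpoint_criterion(st), 0)
  sw <- st; sw$mu_A <- st$mu_B; sw$mu_B <- st$mu_A
  expect_equal(midpoint_criterion(sw), midpoint_criterion(st))
  st$mu_B <- NA_real_
  expect_error(midpoint_criterion(st), "warm|defined")
})

test_that("EWMA criterion updates match the incremental half-step form", {
  # z_{n+1} = z_n + (alpha/2) (X - mu_hat) on trials of the updated category
  set.seed(36)
  alpha <- 0.4
  st <- new_criterion_state("ewma")
  st <- ewma_update(st, -12, "A", alpha)
  st <- ewma_update(st, 9, "B", alpha)
  z <- midpoint_criterion(st)
  for (i in 1:100) {
    cat_i <- sample(c("A", "B"), 1)
    x <- rnorm(1, ifelse(cat_i == "A", -12, 9), 10)
    mu_before <- if (cat_i == "A") st$mu_A else st$mu_B
    st <- ewma_update(st, x, cat_i, alpha)
    z_incr <- z + 0.5 * alpha * (x - mu_before)
    z <- midpoint_criterion(st)
    expect_equal(z, z_incr, tolerance = 1e-10)
  }
})

test_that("covert choice probability is the probit of the criterion-stimulus gap", {
  expect_equal(covert_choice_probability(5, 5, 3), 0.5)
  expect_gt(covert_choice_probability(5, -60, 3), 0.999)
  # monotone decreasing in the stimulus
  p <- covert_choice_probability(0, seq(-20, 20, 2), 4)
  expect_true(all(diff(p) < 0))
  # zero-noise step function
  expect_equal(covert_choice_probability(0, c(-1, 0, 1), 0), c(1, 0.5, 0))
  # Monte-Carlo frequency oracle
  set.seed(37)
  n <- 1e6
  x <- rnorm(n, 2, 4)
  p_mc <- mean(x < 3)
  p_th <- covert_choice_probability(3, 2, 4)
  expect_lt(abs(p_mc - p_th), 3 * sqrt(p_th * (1 - p_th) / n))
})

test_that("alpha and the EWMA time constant are exact inverses", {
  expect_equal(alpha_to_tau(1 - exp(-1)), 1)
  expect_equal(alpha_to_tau(0.5), 1 / log(2))
  a <- seq(0.05, 0.95, by = 0.05)
  expect_equal(tau_to_alpha(alpha_to_tau(a)), a, tolerance = 1e-12)
  expect_true(all(diff(alpha_to_tau(a)) < 0))
  expect_identical(alpha_to_tau(1), 0)
  expect_identical(alpha_to_tau(0), Inf)
})
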