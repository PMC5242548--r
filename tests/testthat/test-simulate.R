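test_that("covert sessions have the stated block structure and are reproducible", {
  cfg <- static_config()
  s1 <- covert_ewma_session()
  expect_equal(nrow(s1), 600)
  expect_setequal(unique(s1$true_category), c("A", "B"))
  s2 <- simulate_covert_session("ewma", list(alpha = 0.3), cfg, seed = 101)
  expect_identical(s1, s2)
  # all logged orientations in (-90, 90]
  for (col in c("stimulus_deg", "measurement_deg", "mu_A", "mu_B")) {
    expect_true(all(s1[[col]] > -90 & s1[[col]] <= 90), label = col)
  }
})

test_that("the closed loop replays exactly from the log", {
  # the criterion logged on trial n must be reproducible from trials < n
  sess <- covert_ewma_session()
  z <- criterion_trajectory("ewma", list(alpha = 0.3), sess, "covert")
  expect_equal(z, sess$criterion_deg, tolerance = 1e-10)

  cfg <- static_config()
  ov <- simulate_overt_session("delta_rule", list(beta = 0.4), cfg, seed = 55)
  zt <- criterion_trajectory("delta_rule", list(beta = 0.4), ov, "overt",
                             z_init = 0)
  expect_equal(zt, ov$theta_c_deg, tolerance = 1e-10)

  dyn <- dynamic_config()
  dk <- simulate_covert_session("kalman", list(r = 0.25), dyn, seed = 56)
  zk <- criterion_trajectory("kalman", list(r = 0.25), dk, "covert")
  expect_equal(zk, dk$criterion_deg, tolerance = 1e-10)

  ob <- simulate_overt_session("bayes_selection", list(), cfg, seed = 57)
  zb <- criterion_trajectory("bayes_selection", list(), ob, "overt")
  expect_equal(zb, ob$theta_c_deg, tolerance = 1e-10)
})

test_that("noiseless EWMA(alpha = 1) responds deterministically and correctly", {
  cfg <- static_config(n_trials = 100, sigma_v = 0, delta_theta = 30,
                       sigma_category = 1e-9)
  s <- simulate_covert_session("ewma", list(alpha = 1), cfg, seed = 61)
  # once both categories are seen, every response is correct: stimuli sit at
  # the category means and the criterion at their midpoint
  both_seen <- which(duplicated(s$true_category) &
                       seq_len(nrow(s)) > match("B", s$true_category) &
                       seq_len(nrow(s)) > match("A", s$true_category))
  expect_true(all(s$correct[both_seen]))
})

test_that("classification at the optimal criterion hits the d'=1 rate", {
  # equal-variance SDT: best possible percent correct is Phi(d'/2)
  cfg <- static_config(n_trials = 4000, sigma_v = 6)
  s <- simulate_covert_session("ewma", list(alpha = 0.2), cfg, seed = 62)
  opt <- omniscient_criterion(s)
  pick_A <- arc_diff(opt, s$measurement_deg) > 0
  pc <- mean(pick_A == (s$true_category == "A"))
  expect_equal(pc, pnorm(0.5), tolerance = 0.025)
})

test_that("overt settings equal the last-sample midpoint for noiseless limited memory", {
  ov <- overt_lm_session(sigma_a = 0)
  n <- nrow(ov)
  for (t in sample(20:n, 25)) {
    past <- ov[seq_len(t - 1), ]
    la <- rev(past$stimulus_deg[past$true_category == "A"])[1]
    lb <- rev(past$stimulus_deg[past$true_category == "B"])[1]
    if (!is.na(la) && !is.na(lb)) {
      expect_equal(ov$criterion_deg[t],
                   wrap_orientation(la + arc_diff(lb, la) / 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("slow-EWMA overt settings converge toward the optimal criterion", {
  cfg <- static_config(sigma_a = 1)
  ov <- simulate_overt_session("ewma", list(alpha = 0.05), cfg, seed = 63)
  opt <- omniscient_criterion(ov)
  rmse <- function(idx) sqrt(mean(arc_diff(ov$criterion_deg[idx], opt[idx])^2))
  expect_lt(rmse(501:600), 0.5 * rmse(1:100))
})

test_that("delta-rule overt settings stay put after correct trials", {
  cfg <- static_config(sigma_a = 0)
  ov <- simulate_overt_session("delta_rule", list(beta = 0.5), cfg, seed = 64)
  after_correct <- which(ov$correct[-nrow(ov)])
  expect_equal(ov$criterion_deg[after_correct + 1],
               ov$criterion_deg[after_correct], tolerance = 1e-10)
})

test_that("dynamic sessions preserve the category separation on every trial", {
  dyn <- dynamic_config()
  s <- simulate_covert_session("ewma", list(alpha = 0.3), dyn, seed = 65)
  seps <- arc_diff(s$mu_B, s$mu_A)
  expect_equal(seps, rep(seps[1], nrow(s)), tolerance = 1e-10)
  expect_true(all(s$mu_A > -90 & s$mu_A <= 90))
})

test_that("discrimination staircases run 4 x 65 trials and obey their rules", {
  sc <- simulate_discrimination_staircase(6, lapse = 0.02, seed = 71)
  expect_equal(nrow(sc), 260)
  expect_equal(as.vector(table(sc$staircase)), rep(65L, 4))
  # noiseless observer descends to the floor level and never errs
  sc0 <- simulate_discrimination_staircase(0, lapse = 0, seed = 72)
  expect_true(all(sc0$correct))
  last <- sc0[sc0$trial > 200, ]
  expect_lt(min(last$delta_theta), 0.26)
})

test_that("an isolated 1-up-2-down staircase tracks 70.7% correct", {
  cfgs <- staircase_config(rules = "one_up_two_down",
                           trials_per_staircase = 4000)
  sc <- simulate_discrimination_staircase(6, staircase = cfgs, lapse = 0,
                                          seed = 73)
  eq <- sc$correct[1001:4000]
  expect_equal(mean(eq), 0.707, tolerance = 0.03)
})

test_that("matching sessions have uniform targets and the stated noise", {
  m0 <- simulate_matching_session(0, seed = 81)
  expect_equal(nrow(m0), 260)
  expect_identical(m0$setting_deg, m0$target_deg)
  m <- simulate_matching_session(7.2, n_trials = 2000, seed = 82)
  err <- arc_diff(m$setting_deg, m$target_deg)
  expect_equal(sd(err), 7.2, tolerance = 0.05 * 7.2)
})
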