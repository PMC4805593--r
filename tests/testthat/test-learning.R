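test_that("the delta rule moves values toward outcomes and fixes the endpoints", {
  expect_equal(q_update(0.5, 1, 0.1), 0.55)
  expect_equal(q_update(0.5, 0, 0.1), 0.45)
  expect_equal(q_update(1, 1, 0.3), 1)
  expect_equal(q_update(0, 0, 0.3), 0)
  expect_error(q_update(1.2, 1, 0.1))
})

test_that("phasic feedback shifts only the chosen action's sensitivities", {
  lp <- learning_params(delta = 0.02)
  st <- learning_state()
  st1 <- gains_update(st, "a_opt", 1, lp)
  expect_equal(st1$gains["a_opt", ], c(direct = 1.02, indirect = 0.98))
  expect_equal(st1$gains["a_sub", ], c(direct = 1, indirect = 1))
  expect_equal(st1$q_opt, q_update(0.5, 1, lp$alpha_q))
  expect_equal(st1$q_sub, 0.5)

  # negative outcome reverses the sign
  st2 <- gains_update(st, "a_sub", 0, lp)
  expect_equal(st2$gains["a_sub", ], c(direct = 0.98, indirect = 1.02))

  # alternating 1, 0 feedback returns the gains to the start
  st3 <- gains_update(gains_update(st, "a_opt", 1, lp), "a_opt", 0, lp)
  expect_equal(st3$gains, st$gains)

  # clamping: no overshoot past the bounds
  lp2 <- learning_params(delta = 0.4, gain_bounds = c(0.8, 1.2))
  st4 <- gains_update(gains_update(st, "a_opt", 1, lp2), "a_opt", 1, lp2)
  expect_equal(unname(st4$gains["a_opt", "direct"]), 1.2)
  expect_equal(unname(st4$gains["a_opt", "indirect"]), 0.8)
})

test_that("drift rates are the documented linear, odd map of the value difference", {
  lp <- learning_params(drift_map_slope = 1, drift_base = 0.1)
  st <- learning_state()
  expect_equal(unname(drift_rates(st, lp)), c(0.1, 0.1))

  st$q_opt <- 0.7; st$q_sub <- 0.3
  expect_equal(unname(drift_rates(st, lp)), c(0.3, -0.1))

  for (qd in c(-0.4, -0.1, 0.2, 0.5)) {
    st$q_opt <- 0.5 + qd / 2; st$q_sub <- 0.5 - qd / 2
    d <- drift_rates(st, lp)
    expect_equal(unname(d[1] - d[2]), qd, tolerance = 1e-12)
  }
})

test_that("first-passage sampler matches the Euler-simulated diffusion", {
  # oracle: discretized single-bound diffusion at small dt
  v <- 0.003; a <- 1; sd <- 0.045
  set.seed(1)
  n <- 3000
  euler <- vapply(seq_len(n), function(k) {
    x <- 0
    for (t in 1:4000) {
      x <- x + v + sd * rnorm(1)
      if (x >= a) return(t)
    }
    NA_real_
  }, numeric(1))
  set.seed(2)
  exact <- bgcompete:::rfpt_drift(n, v, a, sd)
  exact[!is.finite(exact)] <- NA
  expect_equal(mean(euler, na.rm = TRUE), mean(exact, na.rm = TRUE),
               tolerance = 0.05)
  qs <- c(0.25, 0.5, 0.75)
  expect_equal(unname(quantile(euler, qs, na.rm = TRUE)),
               unname(quantile(exact, qs, na.rm = TRUE)), tolerance = 0.08)

  # negative drift: crossing probability matches exp(2 v a / sd^2)
  set.seed(3)
  neg <- bgcompete:::rfpt_drift(4000, -0.002, a, sd)
  p_hat <- mean(is.finite(neg))
  p_theory <- exp(2 * -0.002 * a / sd^2)
  expect_equal(p_hat, p_theory, tolerance = 0.05)
})

test_that("deterministic 1/0 schedule gives monotone value separation with the exact delta-rule path", {
  rs <- reward_schedule(1, 0, n_trials = 600)
  lp <- learning_params()
  tr <- run_learning_session(rs, lp, seed = 4)
  expect_true(all(diff(tr$q_diff) >= -1e-12))
  expect_gt(tr$q_diff[600], 0.8)
  # closed form: q_opt after k choices of a_opt is 1 - 0.5 (1 - alpha)^k
  k_opt <- cumsum(tr$choice == "a_opt")
  expect_equal(tr$q_opt, 1 - 0.5 * (1 - lp$alpha_q)^k_opt, tolerance = 1e-12)
  k_sub <- cumsum(tr$choice == "a_sub")
  expect_equal(tr$q_sub, 0.5 * (1 - lp$alpha_q)^k_sub, tolerance = 1e-12)
})

test_that("equal reward probabilities leave the value difference centered on zero", {
  rs <- reward_schedule(0.5, 0.5, n_trials = 300)
  lp <- learning_params()
  term <- vapply(1:40, function(s)
    run_learning_session(rs, lp, seed = s)$q_diff[300], numeric(1))
  se <- sd(term) / sqrt(length(term))
  expect_lt(abs(mean(term)), 4 * se + 0.02)
})

test_that("values converge to the true reward probabilities under persistent sampling", {
  rs <- reward_schedule(0.8, 0.2, n_trials = 800)
  lp <- learning_params()
  ends <- t(vapply(1:30, function(s) {
    tr <- run_learning_session(rs, lp, seed = s)
    c(tr$q_opt[800], tr$q_sub[800])
  }, numeric(2)))
  expect_lt(abs(mean(ends[, 1]) - 0.8), 0.05)
  expect_lt(abs(mean(ends[, 2]) - 0.2), 0.05)
})

test_that("a larger reward-probability gap is learned faster and preferred sooner", {
  lp <- learning_params()
  med_ttc <- vapply(schedule_presets(600), function(rs) {
    ttcs <- vapply(1:25, function(s)
      as.double(trials_to_criterion(run_learning_session(rs, lp, seed = s),
                                    criterion = 0.15, dwell = 5)),
      numeric(1))
    median(ttcs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_ttc) > 0))

  # preference emerges within sessions
  tr <- run_learning_session(schedule_presets(600)[[1]], lp, seed = 2)
  first_q <- mean(tr$choice[1:150] == "a_opt")
  last_q <- mean(tr$choice[451:600] == "a_opt")
  expect_gt(last_q, first_q)
})

test_that("gain asymmetry tracks the net reward history of the optimal action", {
  lp <- learning_params(gain_bounds = c(0, 2))
  tr <- run_learning_session(reward_schedule(0.8, 0.2, 300), lp, seed = 6)
  opt_rows <- tr$choice == "a_opt"
  net <- cumsum(ifelse(opt_rows, ifelse(tr$reward == 1, 1, -1), 0))
  gain_diff <- tr$gain_opt_d - tr$gain_opt_i
  nonzero <- net != 0
  expect_true(all(sign(gain_diff[nonzero]) == sign(net[nonzero])))
})

test_that("trials_to_criterion matches a brute-force scan", {
  flat <- data.frame(q_diff = rep(0, 50))
  expect_true(is.na(trials_to_criterion(flat, 0.5)))

  lin <- data.frame(q_diff = 0.01 * (1:100))
  expect_equal(trials_to_criterion(lin, 0.5, dwell = 1), 50)

  brute <- function(qd, crit, dwell) {
    for (t in seq_len(length(qd) - dwell + 1)) {
      if (all(qd[t:(t + dwell - 1)] >= crit)) return(t)
    }
    NA_integer_
  }
  set.seed(8)
  for (k in 1:100) {
    qd <- cumsum(rnorm(60, 0.01, 0.1))
    crit <- runif(1, 0.05, 0.5)
    dwell <- sample(1:5, 1)
    expect_identical(trials_to_criterion(data.frame(q_diff = qd), crit, dwell),
                     brute(qd, crit, dwell))
  }
})

test_that("the network-backed race prefers the action with sensitized direct pathway", {
  st <- learning_state()
  st$gains["a_opt", ] <- c(1.25, 0.75)
  st$gains["a_sub", ] <- c(0.75, 1.25)
  p <- channel_preset("gonogo")$params
  inp <- channel_input(I_d = 0.5, I_i = 0.5)
  dp <- decision_params()
  choices <- vapply(1:60, function(s)
    run_learning_race(st, p, inp, dp, seed = s)$choice, character(1))
  expect_gt(mean(choices == "a_opt"), 0.5)

  # and agrees in direction with the analytic race at matched values
  lp <- learning_params()
  st$q_opt <- 0.75; st$q_sub <- 0.25
  set.seed(9)
  fast <- vapply(1:200, function(k)
    bgcompete:::race_trial(drift_rates(st, lp), lp)$choice, character(1))
  expect_gt(mean(fast == "a_opt"), 0.5)
})
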