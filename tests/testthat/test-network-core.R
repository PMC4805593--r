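test_that("leak-only dynamics keep the origin fixed and symmetric states symmetric", {
  p <- tl_params()
  zero <- channel_input()
  expect_identical(step_channel(0, 0, p, zero), c(0, 0))

  # swap symmetry: equal state, symmetric params and input -> equal outputs
  inp <- channel_input(I_d = 0.3, I_i = 0.3)
  out <- step_channel(0.7, 0.7, p, inp)
  expect_identical(out[1], out[2])
})

test_that("a single step matches the hand-evaluated update formula", {
  p <- tl_params(w_self = 0.4, w_inh = 0.3, tau = 50, dt = 1)
  inp <- channel_input(I_d = 0.2, I_i = 0.1, I_m = 0.05, I_lambda = 0.02)
  d <- 0.5; i <- 0.5
  # independent arithmetic: u = w_self*x - w_inh*y + g*I_sel + I_m + I_lam,
  # x' = x + dt/tau * (-x + max(u, 0))
  u_d <- 0.4 * d - 0.3 * i + 1 * 0.2 + 0.05 + 0.02
  u_i <- 0.4 * i - 0.3 * d + 1 * 0.1 + 0.05 + 0.02
  expected <- c(d + (1 / 50) * (-d + max(u_d, 0)),
                i + (1 / 50) * (-i + max(u_i, 0)))
  expect_equal(step_channel(d, i, p, inp), expected, tolerance = 1e-15)
})

test_that("step noise enters additively scaled by sqrt(dt)", {
  p <- tl_params(noise_sd = 0.1, dt = 2, tau = 50)
  inp <- channel_input()
  base <- step_channel(0.5, 0.5, p, inp, noise_pair = c(0, 0))
  pert <- step_channel(0.5, 0.5, p, inp, noise_pair = c(1, -1))
  expect_equal(pert[1] - base[1], 0.1 * sqrt(2), tolerance = 1e-12)
  expect_equal(pert[2] - base[2], -0.1 * sqrt(2), tolerance = 1e-12)
})

test_that("step rejects non-finite or negative states", {
  p <- tl_params()
  inp <- channel_input()
  expect_error(step_channel(NaN, 0, p, inp), "invalid state")
  expect_error(step_channel(-0.1, 0, p, inp), "invalid state")
})

test_that("symmetric channels produce exactly mirrored trajectories", {
  # zero noise: d and i follow identical operations, so equality is exact
  tr <- simulate_channel(
    channel_params(tau = 100, w_self = 1.5, w_inh = 1.5,
                   activation = activation_logistic(4, 1, 1), noise_sd = 0),
    channel_input(I_d = 0.6, I_i = 0.6), horizon = 1000, seed = 1)
  expect_identical(tr$d_rate, tr$i_rate)

  # exchanging (I_d, g_d) with (I_i, g_i) mirrors the zero-noise trajectory
  p1 <- channel_params(tau = 100, w_self = 1.5, w_inh = 1.5, g_d = 1.2,
                       g_i = 0.8, activation = activation_logistic(4, 1, 1),
                       noise_sd = 0)
  p2 <- channel_params(tau = 100, w_self = 1.5, w_inh = 1.5, g_d = 0.8,
                       g_i = 1.2, activation = activation_logistic(4, 1, 1),
                       noise_sd = 0)
  t1 <- simulate_channel(p1, channel_input(I_d = 0.7, I_i = 0.5),
                         horizon = 800, seed = 1)
  t2 <- simulate_channel(p2, channel_input(I_d = 0.5, I_i = 0.7),
                         horizon = 800, seed = 1)
  expect_identical(t1$d_rate, t2$i_rate)
  expect_identical(t1$i_rate, t2$d_rate)
})

test_that("trajectories are deterministic under a fixed seed and non-negative", {
  t1 <- simulate_channel(bi$params, bi$input, horizon = 500, seed = 11)
  t2 <- simulate_channel(bi$params, bi$input, horizon = 500, seed = 11)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  expect_true(all(t1$d_rate >= 0) && all(t1$i_rate >= 0))
  expect_length(t1$times, 501L)

  t3 <- simulate_channel(bi$params, bi$input, horizon = 500, seed = 12)
  expect_false(identical(t1$d_rate, t3$d_rate))
})

test_that("stronger direct input makes the direct pathway diverge earlier", {
  p <- channel_preset("gonogo")$params
  p$noise_sd <- 0
  first_div <- function(ratio) {
    tr <- simulate_channel(p, ratio_input(ratio), horizon = 1200, seed = 1)
    min(which(tr$d_rate - tr$i_rate > 0.1))
  }
  divs <- vapply(c(1.2, 1.6, 2.2, 3), first_div, numeric(1))
  expect_true(all(diff(divs) < 0))
})

test_that("modulatory input raises early activity of both populations", {
  p <- channel_preset("gonogo")$params
  p$noise_sd <- 0
  base <- simulate_channel(p, channel_input(I_d = 0.5, I_i = 0.45),
                           horizon = 300, seed = 1)
  primed <- simulate_channel(p, channel_input(I_d = 0.5, I_i = 0.45, I_m = 0.2),
                             horizon = 300, seed = 1)
  early <- 50:150
  expect_true(all(primed$d_rate[early] > base$d_rate[early]))
  expect_true(all(primed$i_rate[early] > base$i_rate[early]))
})

test_that("divergent dynamics raise an instability error naming the time", {
  # self-excitation > 1 with threshold-linear growth is unbounded
  p <- channel_params(tau = 50, w_self = 3, w_inh = 0, noise_sd = 0, dt = 1,
                      ceiling = 5)
  expect_error(simulate_channel(p, channel_input(I_d = 2), horizon = 2000),
               "ceiling.*at t = [0-9]+ ms")
})

test_that("halving the step leaves zero-noise trajectories nearly unchanged", {
  p1 <- channel_preset("gonogo")$params
  p1$noise_sd <- 0
  p2 <- p1
  p2$dt <- p1$dt / 10
  t1 <- simulate_channel(p1, ratio_input(1.8), horizon = 800, seed = 1)
  t2 <- simulate_channel(p2, ratio_input(1.8), horizon = 800, seed = 1)
  idx2 <- seq(1, length(t2$times), by = 10)
  expect_equal(t2$times[idx2], t1$times)
  expect_lt(max(abs(t1$d_rate - t2$d_rate[idx2])), 0.02)
  expect_lt(max(abs(t1$i_rate - t2$i_rate[idx2])), 0.02)
})

test_that("gate_time finds sustained separations and ignores unsustained ones", {
  # perfectly symmetric trajectory: never separates
  sym <- synthetic_trajectory(0:100, rep(0.5, 101), rep(0.5, 101))
  expect_true(is.na(gate_time(sym, separation = 0.01)))

  # linear ramp d - i = c * t crosses at separation / c
  ramp <- synthetic_trajectory(0:1000, 0.002 * (0:1000), rep(0, 1001))
  expect_equal(gate_time(ramp, separation = 0.4, dwell = 50), 200)

  # a transient crossing shorter than the dwell window is not a gate
  gap <- rep(0, 501)
  gap[100:110] <- 0.5
  gap[300:501] <- 0.5
  blip <- synthetic_trajectory(0:500, gap, rep(0, 501))
  expect_equal(gate_time(blip, separation = 0.4, dwell = 50), 299)
})

test_that("gate time is non-increasing in the input ratio (zero noise)", {
  p <- channel_preset("gonogo")$params
  p$noise_sd <- 0
  gates <- vapply(c(1.2, 1.5, 2, 3, 5), function(r) {
    gate_time(simulate_channel(p, ratio_input(r), horizon = 1200, seed = 1),
              separation = 0.2, dwell = 50)
  }, numeric(1))
  expect_true(all(is.finite(gates)))
  expect_true(all(diff(gates) <= 0))
})

test_that("leak-dominated regime has a single stable equilibrium at the origin", {
  pre <- channel_preset("leak")
  fp <- find_fixed_points(pre$params, pre$input)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$stability, "stable")
  expect_equal(c(fp$d, fp$i), c(0, 0), tolerance = 1e-8)
})

test_that("strong self-excitation yields two attractors and a symmetric saddle", {
  fp <- find_fixed_points(bi$params, bi$input)
  expect_equal(nrow(fp), 3L)
  expect_equal(sum(fp$stability == "stable"), 2L)
  expect_equal(sum(fp$stability == "saddle"), 1L)
  # symmetric problem: point set closed under (d, i) -> (i, d)
  for (k in seq_len(nrow(fp))) {
    mirrored <- any(abs(fp$d - fp$i[k]) < 1e-6 & abs(fp$i - fp$d[k]) < 1e-6)
    expect_true(mirrored)
  }
  # the saddle sits on the diagonal
  sad <- fp[fp$stability == "saddle", ]
  expect_equal(sad$d, sad$i, tolerance = 1e-8)
})

test_that("fixed points agree with a dense-grid forward-integration oracle", {
  # oracle: integrate the zero-noise dynamics from many initial conditions
  # and cluster the terminal states
  p <- bi$params
  p$noise_sd <- 0
  terminals <- list()
  for (d0 in seq(0, 1, length.out = 7)) {
    for (i0 in seq(0, 1, length.out = 7)) {
      # exactly symmetric starts lie on the saddle's stable manifold and
      # never leave the diagonal without noise; skip them
      if (d0 == i0) next
      tr <- simulate_channel(p, bi$input, horizon = 4000, seed = 1,
                             init = c(d0, i0))
      n <- length(tr$times)
      terminals[[length(terminals) + 1L]] <- c(tr$d_rate[n], tr$i_rate[n])
    }
  }
  term <- unique(round(do.call(rbind, terminals), 3))
  fp <- find_fixed_points(bi$params, bi$input)
  stable <- fp[fp$stability == "stable", c("d", "i")]
  # every reached terminal state is one of the reported stable points
  for (k in seq_len(nrow(term))) {
    dist <- sqrt((stable$d - term[k, 1])^2 + (stable$i - term[k, 2])^2)
    expect_lt(min(dist), 0.02)
  }
  # and both stable points are reached from some initial condition
  for (k in seq_len(nrow(stable))) {
    dist <- sqrt((term[, 1] - stable$d[k])^2 + (term[, 2] - stable$i[k])^2)
    expect_lt(min(dist), 0.02)
  }
})

test_that("noise flips the symmetric network into both attractors", {
  wins <- vapply(1:100, function(s) {
    tr <- simulate_channel(bi$params, bi$input, horizon = 1500, seed = s)
    n <- length(tr$times)
    tr$d_rate[n] > tr$i_rate[n]
  }, logical(1))
  expect_gt(mean(wins), 0.1)
  expect_lt(mean(wins), 0.9)
})
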