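#' One Euler-Maruyama step of the channel dynamics
#'
#' Advances the direct/indirect rate pair by one integration step `dt`.
#' Mostly useful for inspection and hand-verification; [simulate_channel()]
#' integrates whole trajectories.
#'
#' @param d,i Current direct and indirect rates (>= 0).
#' @param params A [channel_params()] object.
#' @param input A [channel_input()] object.
#' @param noise_pair Two standard-normal draws (direct, indirect); defaults
#'   to zero noise.
#' @return Numeric vector `c(d, i)` of rectified next-state rates.
#' @examples
#' p <- channel_params(noise_sd = 0)
#' step_channel(0.5, 0.5, p, channel_input(I_d = 1, I_i = 1))
#' @export
step_channel <- function(d, i, params, input, noise_pair = c(0, 0)) {
  stopifnot(inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"),
            length(noise_pair) == 2L)
  if (!all(is.finite(c(d, i))) || d < 0 || i < 0)
    stop("invalid state: rates must be finite and >= 0")
  drive <- net_drive(params, input)
  u_d <- params$w_self * d - params$w_inh * i + drive$d
  u_i <- params$w_self * i - params$w_inh * d + drive$i
  if (params$lambda_mode == "gain") {
    u_d <- u_d * drive$gain
    u_i <- u_i * drive$gain
  }
  f <- params$activation
  sdt <- params$noise_sd * sqrt(params$dt)
  d2 <- d + (params$dt / params$tau) * (-d + act_eval(f, u_d)) + sdt * noise_pair[1]
  i2 <- i + (params$dt / params$tau) * (-i + act_eval(f, u_i)) + sdt * noise_pair[2]
  c(max(d2, 0), max(i2, 0))
}

# Constant part of the net input for each population, resolved once per
# simulation.  With lambda_mode = "gain" the tonic term becomes a gain
# factor rather than a summand.
net_drive <- function(params, input) {
  ns_d <- if (params$ns_weighted) params$g_d else 1
  ns_i <- if (params$ns_weighted) params$g_i else 1
  additive_lambda <- params$lambda_mode == "additive"
  lam_d <- if (additive_lambda) ns_d * input$I_lambda else 0
  lam_i <- if (additive_lambda) ns_i * input$I_lambda else 0
  list(
    d = params$g_d * input$I_d + ns_d * input$I_m + lam_d,
    i = params$g_i * input$I_i + ns_i * input$I_m + lam_i,
    gain = if (additive_lambda) 1 else 1 + input$I_lambda
  )
}

#' Simulate one action channel
#'
#' Integrates the two-population mutual-inhibition dynamics from rest
#' (`d = i = 0` by default) for `horizon` ms with step `params$dt`,
#' using the Euler-Maruyama scheme with additive Gaussian noise and
#' rectification at zero.  The same seed, parameters and input always give
#' a bit-identical trajectory.
#'
#' @inheritParams step_channel
#' @param horizon Simulated duration, ms (>= `params$dt`).
#' @param seed Integer seed for the trajectory's noise stream.
#' @param init Initial `c(d, i)` state.
#' @return An object of class `bg_trajectory`: list with `times` (ms),
#'   `d_rate`, `i_rate`, `seed` and `params_fingerprint`.
#' @examples
#' pre <- channel_preset("gonogo")
#' tr <- simulate_channel(pre$params, pre$input, horizon = 500, seed = 1)
#' tr
#' @export
simulate_channel <- function(params, input, horizon = 1500, seed = 1L,
                             init = c(0, 0)) {
  stopifnot(inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"),
            horizon >= params$dt, length(init) == 2L, all(init >= 0))
  nsteps <- as.integer(ceiling(horizon / params$dt))
  eps <- channel_noise(params, nsteps, n_trials = 1L, seed = seed)
  st <- integrate_channel(init[1], init[2], params, input, nsteps,
                          eps_d = eps$d, eps_i = eps$i, keep_path = TRUE)
  structure(list(times = seq(0, by = params$dt, length.out = nsteps + 1L),
                 d_rate = st$d_path[, 1L], i_rate = st$i_path[, 1L],
                 seed = as.integer(seed),
                 params_fingerprint = params_fingerprint(params, input)),
            class = "bg_trajectory")
}

# Draw the per-step standard-normal noise for n_trials trials as
# nsteps x n_trials matrices (direct first, then indirect), all from one
# seed so the single-trial and vectorized paths consume identical draws.
channel_noise <- function(params, nsteps, n_trials, seed) {
  if (params$noise_sd == 0)
    return(list(d = matrix(0, nsteps, n_trials), i = matrix(0, nsteps, n_trials)))
  d <- matrix(0, nsteps, n_trials)
  i <- matrix(0, nsteps, n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(if (n_trials == 1L) seed else derive_seed(seed, "trial-noise", k - 1L))
    e <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
    d[, k] <- e[, 1L]
    i[, k] <- e[, 2L]
  }
  list(d = d, i = i)
}

# Vectorized integrator: advances n trials in lock-step.  Returns terminal
# states and, optionally, the full paths ((nsteps+1) x n matrices) or a
# streamed evidence accumulator (see decision_readout).
integrate_channel <- function(d0, i0, params, input, nsteps, eps_d, eps_i,
                              keep_path = FALSE) {
  n <- ncol(eps_d)
  d <- rep_len(d0, n)
  i <- rep_len(i0, n)
  drive <- net_drive(params, input)
  gain <- drive$gain
  f <- params$activation
  dt_tau <- params$dt / params$tau
  sdt <- params$noise_sd * sqrt(params$dt)
  d_path <- i_path <- NULL
  if (keep_path) {
    d_path <- matrix(NA_real_, nsteps + 1L, n)
    i_path <- matrix(NA_real_, nsteps + 1L, n)
    d_path[1L, ] <- d
    i_path[1L, ] <- i
  }
  for (t in seq_len(nsteps)) {
    u_d <- (params$w_self * d - params$w_inh * i + drive$d) * gain
    u_i <- (params$w_self * i - params$w_inh * d + drive$i) * gain
    d <- pmax(d + dt_tau * (-d + act_eval(f, u_d)) + sdt * eps_d[t, ], 0)
    i <- pmax(i + dt_tau * (-i + act_eval(f, u_i)) + sdt * eps_i[t, ], 0)
    bad <- d > params$ceiling | i > params$ceiling
    if (any(bad))
      stop("unstable dynamics: activity exceeded ceiling ", params$ceiling,
           " at t = ", t * params$dt, " ms (trial ", which(bad)[1], ")")
    if (keep_path) {
      d_path[t + 1L, ] <- d
      i_path[t + 1L, ] <- i
    }
  }
  list(d = d, i = i, d_path = d_path, i_path = i_path)
}

#' @export
print.bg_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<bg_trajectory> %d samples over %g ms (seed %d)\n",
              n, x$times[n], x$seed))
  cat(sprintf("  terminal d = %.4f, i = %.4f; params %s\n",
              x$d_rate[n], x$i_rate[n], x$params_fingerprint))
  invisible(x)
}

#' @export
as.data.frame.bg_trajectory <- function(x, ...) {
  data.frame(time_ms = x$times, d_rate = x$d_rate, i_rate = x$i_rate)
}

#' Gate time of a trajectory
#'
#' The "gate" is the moment the two pathways' firing rates nonlinearly
#' separate, marking the transition from deliberation toward commitment.
#' Operationally: the first time at which `|d - i| >= separation` and the
#' separation is sustained for a dwell window (guarding against transient
#' noise-driven crossings).
#'
#' @param traj A [simulate_channel()] trajectory.
#' @param separation Rate-difference criterion (> 0).
#' @param dwell Dwell window, ms; the criterion must hold at every sample in
#'   `[t, t + dwell]` (or to the end of the trajectory if it ends sooner).
#' @return Gate time in ms, or `NA_real_` if the trajectory never separates.
#' @export
gate_time <- function(traj, separation, dwell = 50) {
  stopifnot(inherits(traj, "bg_trajectory"), separation > 0, dwell >= 0)
  gap <- abs(traj$d_rate - traj$i_rate) >= separation
  if (!any(gap)) return(NA_real_)
  dt <- traj$times[2] - traj$times[1]
  win <- max(1L, as.integer(round(dwell / dt)))
  n <- length(gap)
  # first index from which gap holds for win consecutive samples (or to end)
  for (t in which(gap)) {
    t_end <- min(n, t + win)
    if (all(gap[t:t_end])) return(traj$times[t])
  }
  NA_real_
}
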