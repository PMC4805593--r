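#' Reward schedule of the probabilistic selection task
#'
#' Two stimuli with Bernoulli reward probabilities; the optimal one
#' (`p_opt`) pays off more often than the suboptimal one (`p_sub`).
#' The conventional probability pairs 0.80/0.20, 0.70/0.30 and 0.60/0.40
#' are available as presets via [schedule_presets()].
#'
#' @param p_opt,p_sub Reward probabilities in \[0, 1\], `p_opt >= p_sub`.
#' @param n_trials Session length (>= 1).
#' @return An object of class `bg_reward_schedule`.
#' @export
reward_schedule <- function(p_opt, p_sub, n_trials = 200) {
  stopifnot(p_opt >= 0, p_opt <= 1, p_sub >= 0, p_sub <= 1, n_trials >= 1)
  if (p_opt < p_sub) stop("p_opt must be >= p_sub")
  structure(list(p_opt = p_opt, p_sub = p_sub,
                 n_trials = as.integer(n_trials)),
            class = "bg_reward_schedule")
}

#' @rdname reward_schedule
#' @param n_trials Session length shared by the three presets.
#' @return `schedule_presets()`: named list of the three conventional
#'   schedules, ordered by decreasing reward-probability gap.
#' @export
schedule_presets <- function(n_trials = 200) {
  list(`0.80/0.20` = reward_schedule(0.80, 0.20, n_trials),
       `0.70/0.30` = reward_schedule(0.70, 0.30, n_trials),
       `0.60/0.40` = reward_schedule(0.60, 0.40, n_trials))
}

#' Reinforcement-learning parameters
#'
#' Phasic feedback is modelled at two coupled levels.  The abstract level
#' keeps delta-rule action values `Q(a)` whose difference maps linearly to
#' the drift rates of a two-accumulator race.  The network level keeps
#' per-action pathway sensitivities (direct, indirect), nudged by a fixed
#' increment `delta` after every feedback event: a reward sensitizes the
#' chosen action's direct pathway and desensitizes its indirect pathway
#' (`+delta`/`-delta`), and a non-reward does the opposite.  Optionally
#' the increment scales with the magnitude of the reward-prediction error
#' (`rpe_scaled = TRUE`).
#'
#' @param alpha_q Value learning rate in (0, 1].
#' @param delta Pathway-sensitivity increment per feedback event (> 0).
#' @param drift_map_slope Scale from value difference to drift-rate
#'   difference (evidence/ms per unit of value).
#' @param drift_base Drift shared by both actions at value equality
#'   (evidence/ms).
#' @param gain_bounds Clamp interval for the pathway sensitivities.
#' @param boundary Race boundary (evidence units > 0).
#' @param race_noise_sd Diffusion coefficient of each race accumulator
#'   (evidence per sqrt(ms)).
#' @param deadline Race deadline, ms.
#' @param t0 Non-decision time, ms.
#' @param rpe_scaled If `TRUE`, the sensitivity increment is
#'   `delta * |RPE|` instead of the fixed `delta`.
#' @param lambda_gain Drift multiplier per unit of tonic background drive:
#'   effective drifts are scaled by `1 + lambda_gain * I_lambda`
#'   (exploitation knob; see [run_tonic_sweep()]).
#' @return An object of class `bg_learning_params`.
#' @export
learning_params <- function(alpha_q = 0.05, delta = 0.01,
                            drift_map_slope = 0.004, drift_base = 0.0022,
                            gain_bounds = c(0.25, 1.75),
                            boundary = 1, race_noise_sd = 0.045,
                            deadline = 1500, t0 = 100,
                            rpe_scaled = FALSE, lambda_gain = 1) {
  stopifnot(alpha_q > 0, alpha_q <= 1, delta > 0,
            is.finite(drift_map_slope), is.finite(drift_base),
            length(gain_bounds) == 2L, gain_bounds[1] < gain_bounds[2],
            boundary > 0, race_noise_sd > 0, deadline > t0, t0 >= 0,
            is.logical(rpe_scaled), lambda_gain >= 0)
  structure(list(alpha_q = alpha_q, delta = delta,
                 drift_map_slope = drift_map_slope, drift_base = drift_base,
                 gain_bounds = gain_bounds, boundary = boundary,
                 race_noise_sd = race_noise_sd, deadline = deadline,
                 t0 = t0, rpe_scaled = rpe_scaled, lambda_gain = lambda_gain),
            class = "bg_learning_params")
}

#' Fresh learning state
#'
#' Both actions start with equal values (`q0`) and symmetric unit pathway
#' sensitivities, hence equal drift rates.
#'
#' @param q0 Initial value of both actions.
#' @return An object of class `bg_learning_state`: list with `q_opt`,
#'   `q_sub`, `gains` (2x2 matrix, rows `a_opt`/`a_sub`, columns
#'   `direct`/`indirect`) and `trial_index`.
#' @export
learning_state <- function(q0 = 0.5) {
  stopifnot(q0 >= 0, q0 <= 1)
  structure(list(q_opt = q0, q_sub = q0,
                 gains = matrix(1, 2, 2,
                                dimnames = list(c("a_opt", "a_sub"),
                                                c("direct", "indirect"))),
                 trial_index = 0L),
            class = "bg_learning_state")
}

#' Delta-rule value update
#'
#' `q' = q + alpha_q * (reward - q)`: the update moves the estimate toward
#' the observed outcome by a fraction `alpha_q` of the reward-prediction
#' error, and keeps it in \[0, 1\] for Bernoulli rewards.
#'
#' @param q Current value estimate in \[0, 1\].
#' @param reward Observed outcome, 0 or 1.
#' @param alpha_q Learning rate in (0, 1].
#' @return Updated value.
#' @examples
#' q_update(0.5, 1, 0.1)  # 0.55
#' @export
q_update <- function(q, reward, alpha_q) {
  stopifnot(q >= 0, q <= 1, reward %in% c(0, 1), alpha_q > 0, alpha_q <= 1)
  q + alpha_q * (reward - q)
}

#' Phasic update of pathway sensitivities
#'
#' Applies the dopamine-like feedback rule to the chosen action only:
#' after a reward, its direct-pathway sensitivity increases and its
#' indirect-pathway sensitivity decreases by `delta`; after a non-reward
#' the signs flip.  Results are clamped to `lp$gain_bounds`; the unchosen
#' action is untouched.  The value estimate of the chosen action is also
#' updated with the delta rule.
#'
#' @param state A [learning_state()] object.
#' @param chosen `"a_opt"` or `"a_sub"`.
#' @param reward Observed outcome, 0 or 1.
#' @param lp A [learning_params()] object.
#' @return The updated `bg_learning_state`.
#' @export
gains_update <- function(state, chosen, reward, lp) {
  stopifnot(inherits(state, "bg_learning_state"),
            chosen %in% c("a_opt", "a_sub"), reward %in% c(0, 1),
            inherits(lp, "bg_learning_params"))
  q_old <- if (chosen == "a_opt") state$q_opt else state$q_sub
  rpe <- reward - q_old
  inc <- if (lp$rpe_scaled) lp$delta * abs(rpe) else lp$delta
  sgn <- if (reward == 1) 1 else -1
  g <- state$gains
  g[chosen, "direct"] <- clamp(g[chosen, "direct"] + sgn * inc, lp$gain_bounds)
  g[chosen, "indirect"] <- clamp(g[chosen, "indirect"] - sgn * inc, lp$gain_bounds)
  state$gains <- g
  if (chosen == "a_opt") {
    state$q_opt <- q_update(state$q_opt, reward, lp$alpha_q)
  } else {
    state$q_sub <- q_update(state$q_sub, reward, lp$alpha_q)
  }
  state
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Drift rates implied by the current values
#'
#' The drift of each action's accumulator is the shared base drift plus or
#' minus half the value difference scaled by `drift_map_slope`:
#' `drift_opt = drift_base + slope * (q_opt - q_sub) / 2` and
#' `drift_sub = drift_base - slope * (q_opt - q_sub) / 2`.  At value
#' equality both drifts equal `drift_base`; the drift difference is an
#' odd, linear function of the value difference.
#'
#' @param state A [learning_state()] object.
#' @param lp A [learning_params()] object.
#' @return Named numeric vector `c(drift_opt, drift_sub)` (evidence/ms).
#' @export
drift_rates <- function(state, lp) {
  stopifnot(inherits(state, "bg_learning_state"),
            inherits(lp, "bg_learning_params"))
  half <- lp$drift_map_slope * (state$q_opt - state$q_sub) / 2
  c(drift_opt = lp$drift_base + half, drift_sub = lp$drift_base - half)
}

# --- first-passage race -----------------------------------------------------

# Exact first-passage time of a constant-drift diffusion
# dX = v dt + sd dW through an absorbing bound a > 0 (X0 = 0):
#  * v > 0: inverse-Gaussian(mu = a/v, shape = a^2/sd^2), sampled with the
#    Michael-Schucany-Haas transform;
#  * v < 0: crossing happens with probability exp(2 v a / sd^2); conditioned
#    on crossing, the time is inverse-Gaussian with drift |v|;
#  * v = 0: crossing is almost sure with a Levy-distributed time
#    a^2 / (sd Z)^2.
# Returns Inf for trials that never cross.  Consumes draws from the
# current RNG stream.
rfpt_drift <- function(n, v, a, sd) {
  stopifnot(a > 0, sd > 0)
  out <- numeric(n)
  for (k in seq_len(n)) {
    vk <- if (length(v) > 1) v[k] else v
    if (vk == 0) {
      z <- stats::rnorm(1)
      out[k] <- if (z == 0) Inf else (a / (sd * z))^2
    } else {
      cross <- if (vk > 0) TRUE else stats::runif(1) < exp(2 * vk * a / sd^2)
      if (!cross) { out[k] <- Inf; next }
      mu <- a / abs(vk)
      shape <- a^2 / sd^2
      z <- stats::rnorm(1)
      y <- z^2
      x <- mu + mu^2 * y / (2 * shape) -
        mu / (2 * shape) * sqrt(4 * mu * shape * y + mu^2 * y^2)
      u <- stats::runif(1)
      out[k] <- if (u <= mu / (mu + x)) x else mu^2 / x
    }
  }
  out
}

# One race trial between two constant-drift accumulators; first crossing
# wins, double-timeout is a forced fair guess with rt = NA.  Drifts in
# evidence/ms; returns list(choice = "a_opt"/"a_sub", rt, timeout).
race_trial <- function(drifts, lp, lambda_scale = 1) {
  window <- lp$deadline - lp$t0
  t_opt <- rfpt_drift(1, drifts[["drift_opt"]] * lambda_scale,
                      lp$boundary, lp$race_noise_sd)
  t_sub <- rfpt_drift(1, drifts[["drift_sub"]] * lambda_scale,
                      lp$boundary, lp$race_noise_sd)
  if (t_opt > window && t_sub > window) {
    choice <- if (stats::runif(1) < 0.5) "a_opt" else "a_sub"
    return(list(choice = choice, rt = NA_real_, timeout = TRUE))
  }
  if (t_opt == t_sub) {           # measure-zero tie, resolved randomly
    choice <- if (stats::runif(1) < 0.5) "a_opt" else "a_sub"
    rt <- lp$t0 + t_opt
  } else if (t_opt < t_sub) {
    choice <- "a_opt"; rt <- lp$t0 + t_opt
  } else {
    choice <- "a_sub"; rt <- lp$t0 + t_sub
  }
  list(choice = choice, rt = rt, timeout = FALSE)
}

#' Simulate one learning session
#'
#' Trial loop of the probabilistic selection task: drift rates are derived
#' from the current value estimates, the choice and RT come from a race of
#' two constant-drift stochastic accumulators (first crossing wins;
#' exploration arises from the accumulator noise, not from a softmax), the
#' chosen stimulus pays a Bernoulli reward, and the delta-rule value and
#' phasic sensitivity updates are applied to the chosen action only.
#' Double-timeout trials are a forced fair guess that still receives
#' feedback (configurable via `learn_on_timeout`).
#'
#' The race is sampled exactly: the first-passage time of a constant-drift
#' diffusion through a single absorbing bound is inverse-Gaussian, so no
#' time discretization is involved (see [run_learning_race()] for the
#' network-backed alternative).
#'
#' @param rs A [reward_schedule()] object.
#' @param lp A [learning_params()] object.
#' @param seed Base seed.
#' @param I_lambda Tonic background drive applied during choice expression
#'   (scales both drifts by `1 + lambda_gain * I_lambda`; never alters
#'   learning state updates).
#' @param learn_on_timeout Apply feedback on forced-guess trials (default
#'   `TRUE`).
#' @param q0 Initial value of both actions.
#' @return An object of class `bg_learning_trace`: data frame with columns
#'   `trial`, `choice`, `reward`, `rt_ms`, `timeout`, `q_opt`, `q_sub`,
#'   `q_diff`, `gain_opt_d`, `gain_opt_i`, `gain_sub_d`, `gain_sub_i`
#'   (post-update values), with the schedule and final state as attributes.
#' @examples
#' rs <- reward_schedule(0.8, 0.2, n_trials = 50)
#' tr <- run_learning_session(rs, learning_params(), seed = 1)
#' tail(tr$q_diff, 1)
#' @export
run_learning_session <- function(rs, lp, seed = 1L, I_lambda = 0,
                                 learn_on_timeout = TRUE, q0 = 0.5) {
  stopifnot(inherits(rs, "bg_reward_schedule"),
            inherits(lp, "bg_learning_params"), I_lambda >= 0)
  st <- learning_state(q0)
  n <- rs$n_trials
  lam_scale <- 1 + lp$lambda_gain * I_lambda
  choice <- character(n); reward <- integer(n)
  rt <- numeric(n); timeout <- logical(n)
  qo <- numeric(n); qs <- numeric(n)
  gains <- matrix(NA_real_, n, 4)
  set.seed(derive_seed(seed, "learn-session"))
  for (t in seq_len(n)) {
    drifts <- drift_rates(st, lp)
    race <- race_trial(drifts, lp, lambda_scale = lam_scale)
    p_rew <- if (race$choice == "a_opt") rs$p_opt else rs$p_sub
    r <- as.integer(stats::runif(1) < p_rew)
    if (!race$timeout || learn_on_timeout)
      st <- gains_update(st, race$choice, r, lp)
    st$trial_index <- t
    choice[t] <- race$choice; reward[t] <- r
    rt[t] <- race$rt; timeout[t] <- race$timeout
    qo[t] <- st$q_opt; qs[t] <- st$q_sub
    gains[t, ] <- c(st$gains["a_opt", ], st$gains["a_sub", ])
  }
  out <- data.frame(trial = seq_len(n), choice = choice, reward = reward,
                    rt_ms = rt, timeout = timeout,
                    q_opt = qo, q_sub = qs, q_diff = qo - qs,
                    gain_opt_d = gains[, 1], gain_opt_i = gains[, 2],
                    gain_sub_d = gains[, 3], gain_sub_i = gains[, 4],
                    stringsAsFactors = FALSE)
  structure(out, schedule = rs, params = lp, base_seed = as.integer(seed),
            final_state = st,
            class = c("bg_learning_trace", "data.frame"))
}

#' Network-backed value-based choice trial
#'
#' Alternative choice engine for the learning task: instead of the
#' analytic race, both actions are simulated as full direct/indirect
#' channels whose pathway gains (`g_d`, `g_i`) are the learned
#' sensitivities of [gains_update()], and the first channel whose
#' normalized-difference evidence crosses the execution threshold wins.
#' Slower than the analytic race but mechanistically explicit; the two
#' engines agree in choice preference at matched drifts.
#'
#' @param state A [learning_state()] object supplying the pathway gains.
#' @param params Channel parameter template; `g_d`/`g_i` are overridden by
#'   the learned gains per action.
#' @param input Shared channel input (both actions receive the same
#'   cortical drive; the learned gains carry the value difference).
#' @param dp A [decision_params()] object.
#' @param seed Trial seed.
#' @return list(choice = "a_opt"/"a_sub", rt, timeout)
#' @export
run_learning_race <- function(state, params, input, dp, seed = 1L) {
  stopifnot(inherits(state, "bg_learning_state"),
            inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"),
            inherits(dp, "bg_decision_params"))
  nsteps <- as.integer(ceiling((dp$deadline - dp$t0) / params$dt))
  t_cross <- numeric(2)
  set.seed(seed)
  eps <- list(a_opt = NULL, a_sub = NULL)
  for (a in 1:2) {
    e <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
    eps[[a]] <- list(d = e[, 1L, drop = FALSE], i = e[, 2L, drop = FALSE])
  }
  tie_u <- stats::runif(1)
  for (a in 1:2) {
    pa <- params
    pa$g_d <- params$g_d * state$gains[a, "direct"]
    pa$g_i <- params$g_i * state$gains[a, "indirect"]
    res <- integrate_with_evidence(pa, input, dp, nsteps, eps[[a]])
    t_cross[a] <- if (res$crossed) res$t_cross else Inf
  }
  if (all(!is.finite(t_cross))) {
    return(list(choice = if (tie_u < 0.5) "a_opt" else "a_sub",
                rt = NA_real_, timeout = TRUE))
  }
  win <- if (t_cross[1] == t_cross[2]) (if (tie_u < 0.5) 1L else 2L)
         else which.min(t_cross)
  list(choice = c("a_opt", "a_sub")[win], rt = dp$t0 + t_cross[win],
       timeout = FALSE)
}

#' Trials to a value-difference criterion
#'
#' First trial index from which the estimated value difference stays at or
#' above `criterion` for `dwell` consecutive trials; `NA` if it never does.
#' Operationalizes learning speed: sessions with a larger reward-probability
#' gap reach a fixed criterion sooner.
#'
#' @param trace A [run_learning_session()] trace (or any data frame with a
#'   `q_diff` column).
#' @param criterion Value-difference level (> 0).
#' @param dwell Number of consecutive trials the criterion must hold.
#' @return Trial index (integer) or `NA_integer_`.
#' @export
trials_to_criterion <- function(trace, criterion, dwell = 1L) {
  stopifnot(criterion > 0, dwell >= 1)
  ok <- trace$q_diff >= criterion
  n <- length(ok)
  if (n < dwell) return(NA_integer_)
  for (t in seq_len(n - dwell + 1L)) {
    if (all(ok[t:(t + dwell - 1L)])) return(t)
  }
  NA_integer_
}

#' @export
print.bg_learning_trace <- function(x, ...) {
  rs <- attr(x, "schedule")
  cat(sprintf("<bg_learning_trace> %d trials, schedule %.2f/%.2f\n",
              nrow(x), rs$p_opt, rs$p_sub))
  cat(sprintf("  terminal q_opt = %.3f, q_sub = %.3f, P(a_opt) = %.3f\n",
              x$q_opt[nrow(x)], x$q_sub[nrow(x)], mean(x$choice == "a_opt")))
  invisible(x)
}
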