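#' Decision parameters for the accumulate-to-threshold readout
#'
#' A trial is read out by accumulating the normalized difference of the
#' direct and indirect firing rates,
#' `E(t) = sum beta * (d - i) / (d + i + eps) * dt`,
#' toward an execution threshold `theta`.  If the evidence reaches `theta`
#' by the trial deadline the outcome is "go" with reaction time
#' `t0 + crossing time`; otherwise the outcome is "no-go".  There is a
#' single absorbing upper bound: no-go is a deadline outcome, not a lower
#' boundary, and transiently negative evidence (indirect dominance) never
#' triggers an outcome by itself.  A crossing at exactly the deadline
#' counts as go (closed right endpoint).
#'
#' @param threshold Execution threshold `theta` on accumulated evidence (> 0).
#' @param deadline Trial deadline, ms (> `t0`).
#' @param evidence_gain Scale `beta` applied to the normalized difference,
#'   per ms.
#' @param norm_eps Denominator guard `eps` (rate units > 0) so the
#'   normalized difference degenerates gracefully at rest.
#' @param t0 Non-decision time added to crossing times, ms (>= 0).
#' @param baseline Starting level of the evidence accumulator (default 0).
#' @return An object of class `bg_decision_params`.
#' @export
decision_params <- function(threshold = 1, deadline = 1500,
                            evidence_gain = 0.005, norm_eps = 1e-3,
                            t0 = 100, baseline = 0) {
  stopifnot(is.finite(threshold), threshold > 0,
            is.finite(deadline), is.finite(t0), t0 >= 0, deadline > t0,
            is.finite(evidence_gain), evidence_gain > 0,
            is.finite(norm_eps), norm_eps > 0,
            is.finite(baseline))
  structure(list(threshold = threshold, deadline = deadline,
                 evidence_gain = evidence_gain, norm_eps = norm_eps,
                 t0 = t0, baseline = baseline),
            class = "bg_decision_params")
}

#' Accumulated decision evidence of a trajectory
#'
#' Integrates the normalized direct-indirect rate difference over time
#' (left Riemann sum on the trajectory's own grid).
#'
#' @param traj A [simulate_channel()] trajectory.
#' @param dp A [decision_params()] object.
#' @return An object of class `bg_evidence`: list with `times` and
#'   `evidence`, same length as the trajectory.
#' @export
decision_evidence <- function(traj, dp) {
  stopifnot(inherits(traj, "bg_trajectory"), inherits(dp, "bg_decision_params"))
  dt <- traj$times[2] - traj$times[1]
  inc <- dp$evidence_gain * dt *
    (traj$d_rate - traj$i_rate) / (traj$d_rate + traj$i_rate + dp$norm_eps)
  ev <- dp$baseline + cumsum(c(0, inc[-length(inc)]))
  structure(list(times = traj$times, evidence = ev), class = "bg_evidence")
}

#' Classify one evidence trace into a go/no-go outcome
#'
#' @param ev A [decision_evidence()] trace; must cover `[0, deadline - t0]`.
#' @param dp A [decision_params()] object.
#' @param condition Optional condition tag stored in the outcome.
#' @param seed Optional seed tag stored in the outcome.
#' @return An object of class `bg_trial_outcome`: list with `label`
#'   (`"go"`/`"no-go"`), `rt` (ms, `NA` for no-go), `crossed`, `condition`,
#'   `seed`.
#' @export
classify_trial <- function(ev, dp, condition = NA_character_, seed = NA_integer_) {
  stopifnot(inherits(ev, "bg_evidence"), inherits(dp, "bg_decision_params"))
  horizon_needed <- dp$deadline - dp$t0
  if (max(ev$times) < horizon_needed)
    stop("evidence trace covers only [0, ", max(ev$times),
         "] ms but the decision window requires [0, ", horizon_needed, "] ms")
  in_window <- ev$times <= horizon_needed
  hit <- which(in_window & ev$evidence >= dp$threshold)
  if (length(hit) > 0L) {
    t_cross <- ev$times[hit[1L]]
    out <- list(label = "go", rt = dp$t0 + t_cross, crossed = TRUE,
                condition = condition, seed = seed)
  } else {
    out <- list(label = "no-go", rt = NA_real_, crossed = FALSE,
                condition = condition, seed = seed)
  }
  structure(out, class = "bg_trial_outcome")
}

#' @export
print.bg_trial_outcome <- function(x, ...) {
  cat(sprintf("<bg_trial_outcome> %s%s\n", x$label,
              if (x$crossed) sprintf(" (rt = %g ms)", x$rt) else ""))
  invisible(x)
}

#' Monte-Carlo go/no-go trials for one channel condition
#'
#' Runs `n` independent trials of [simulate_channel()] +
#' [decision_evidence()] + [classify_trial()], with per-trial seeds derived
#' deterministically from the base seed.  Trials are integrated in
#' lock-step (vectorized across trials) using exactly the noise stream each
#' trial would consume on its own, so any single trial can be reproduced
#' with [simulate_channel()] at its recorded seed.
#'
#' @inheritParams simulate_channel
#' @param dp A [decision_params()] object.
#' @param n Number of trials (>= 1).
#' @param condition Condition tag recorded on every trial.
#' @return An object of class `bg_trials`: a data frame with columns
#'   `trial`, `condition`, `label`, `rt_ms`, `crossed`, `seed`, carrying
#'   metadata attributes `params_fingerprint`, `n` and `base_seed`.
#' @examples
#' pre <- channel_preset("gonogo")
#' inp <- channel_input(I_d = 0.55, I_i = 0.35)
#' ts <- run_trials(pre$params, inp, decision_params(), n = 20, seed = 7)
#' summary(ts)
#' @export
run_trials <- function(params, input, dp, n, seed = 1L,
                       condition = NA_character_) {
  stopifnot(inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"),
            inherits(dp, "bg_decision_params"), n >= 1)
  nsteps <- as.integer(ceiling((dp$deadline - dp$t0) / params$dt))
  eps <- channel_noise(params, nsteps, n_trials = n, seed = seed)
  res <- integrate_with_evidence(params, input, dp, nsteps, eps)
  trial_seeds <- if (params$noise_sd == 0) rep(as.integer(seed), n) else
    vapply(seq_len(n) - 1L, function(k) derive_seed(seed, "trial-noise", k),
           integer(1))
  out <- data.frame(
    trial = seq_len(n),
    condition = rep(condition, n),
    label = ifelse(res$crossed, "go", "no-go"),
    rt_ms = ifelse(res$crossed, dp$t0 + res$t_cross, NA_real_),
    crossed = res$crossed,
    seed = trial_seeds,
    stringsAsFactors = FALSE
  )
  new_bg_trials(out, params_fingerprint = params_fingerprint(params, input, dp),
                base_seed = as.integer(seed), kind = "gonogo")
}

new_bg_trials <- function(df, params_fingerprint = NA_character_,
                          base_seed = NA_integer_, kind = "gonogo") {
  structure(df,
            params_fingerprint = params_fingerprint,
            base_seed = base_seed, kind = kind,
            class = c("bg_trials", "data.frame"))
}

# Streamed variant of integrate_channel: accumulates the normalized
# difference and records the first threshold crossing per trial without
# storing full paths.
integrate_with_evidence <- function(params, input, dp, nsteps, eps) {
  n <- ncol(eps$d)
  d <- numeric(n)
  i <- numeric(n)
  ev <- rep(dp$baseline, n)
  t_cross <- rep(NA_real_, n)
  drive <- net_drive(params, input)
  gain <- drive$gain
  f <- params$activation
  dt <- params$dt
  dt_tau <- dt / params$tau
  sdt <- params$noise_sd * sqrt(dt)
  # evidence at sample t uses the state at t-1 (left Riemann sum), and a
  # crossing at sample t maps to trajectory time t*dt
  crossed_now <- ev >= dp$threshold & is.na(t_cross)
  t_cross[crossed_now] <- 0
  for (t in seq_len(nsteps)) {
    ev <- ev + dp$evidence_gain * dt * (d - i) / (d + i + dp$norm_eps)
    u_d <- (params$w_self * d - params$w_inh * i + drive$d) * gain
    u_i <- (params$w_self * i - params$w_inh * d + drive$i) * gain
    d <- pmax(d + dt_tau * (-d + act_eval(f, u_d)) + sdt * eps$d[t, ], 0)
    i <- pmax(i + dt_tau * (-i + act_eval(f, u_i)) + sdt * eps$i[t, ], 0)
    if (any(d > params$ceiling | i > params$ceiling))
      stop("unstable dynamics: activity exceeded ceiling ", params$ceiling,
           " at t = ", t * dt, " ms")
    # ev is now the evidence decision_evidence() reports at time t*dt;
    # closed right endpoint: a crossing at exactly the deadline counts
    if (t * dt <= dp$deadline - dp$t0) {
      crossed_now <- is.na(t_cross) & ev >= dp$threshold
      t_cross[crossed_now] <- t * dt
    }
  }
  list(crossed = !is.na(t_cross), t_cross = t_cross)
}

#' Summary statistics of a trial set
#'
#' Go-rate over all trials plus reaction-time statistics (mean, SD and the
#' 10/30/50/70/90% quantiles) over completed ("go") trials only.  RT
#' statistics are `NA` when no trial completed.
#'
#' @param object A [run_trials()] trial set.
#' @param ... Unused.
#' @return A list with `n`, `go_rate`, `mean_rt`, `sd_rt`, `rt_quantiles`.
#' @export
summary.bg_trials <- function(object, ...) {
  rts <- object$rt_ms[object$crossed]
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  out <- list(
    n = nrow(object),
    go_rate = mean(object$crossed),
    mean_rt = if (length(rts)) mean(rts) else NA_real_,
    sd_rt = if (length(rts) > 1) stats::sd(rts) else NA_real_,
    rt_quantiles = if (length(rts))
      stats::quantile(rts, qs, names = TRUE, type = 7) else
      stats::setNames(rep(NA_real_, 5), paste0(qs * 100, "%"))
  )
  class(out) <- "summary.bg_trials"
  out
}

#' @export
print.summary.bg_trials <- function(x, ...) {
  cat(sprintf("n = %d trials, go-rate = %.3f\n", x$n, x$go_rate))
  if (!is.na(x$mean_rt))
    cat(sprintf("go RT: mean %.1f ms, sd %.1f ms\n", x$mean_rt, x$sd_rt))
  if (!all(is.na(x$rt_quantiles))) {
    cat("RT quantiles (ms):\n")
    print(round(x$rt_quantiles, 1))
  }
  invisible(x)
}

#' @export
print.bg_trials <- function(x, ...) {
  cat(sprintf("<bg_trials:%s> %d trials (base seed %s)\n",
              attr(x, "kind"), nrow(x), attr(x, "base_seed")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more trials\n")
  invisible(x)
}
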