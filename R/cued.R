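#' Parameters of the cued two-alternative forced-choice task
#'
#' Two action channels (left, right) race to the execution threshold.
#' Each channel receives sensory drive with a bias favouring its direct
#' population (sensory cortico-striatal afferents synapse more on direct-
#' than indirect-pathway neurons):
#' `I_d = sensory_gain * direct_bias * (base + coherence * matched)` and
#' `I_i = sensory_gain * (1 - direct_bias) * (base + coherence * matched)`,
#' where `matched` is 1 for the channel encoding the true stimulus
#' direction and 0 otherwise.  Before the stimulus, a modulatory population
#' primes the cued channel with non-selective drive `I_m = cue_strength`,
#' raising its baseline excitability: valid cues speed correct responses,
#' invalid ones destabilize the wrong channel and produce fast errors (the
#' speed-accuracy tradeoff).  The first channel whose evidence crosses the
#' threshold wins; a same-sample tie is resolved uniformly at random from
#' the trial's RNG stream.
#'
#' @param coherence Sensory evidence strength for the true direction (>= 0).
#' @param sensory_base Direction-unspecific component of the sensory drive.
#' @param sensory_gain Scale from sensory activity to channel input.
#' @param direct_bias Fraction of sensory input routed to the direct
#'   population, in (0.5, 1].
#' @param cue_strength Modulatory drive `I_m` delivered to the cued channel.
#' @param cue_validity Probability that the cue matches the upcoming
#'   stimulus, in \[0, 1\].
#' @param channel_params A [channel_params()] object shared by both channels.
#' @param decision_params A [decision_params()] object.
#' @return An object of class `bg_cued_task`.
#' @export
cued_task_params <- function(coherence = 0.3, sensory_base = 1,
                             sensory_gain = 0.9, direct_bias = 0.65,
                             cue_strength = 0.15, cue_validity = 0.8,
                             channel_params = channel_preset("gonogo")$params,
                             decision_params = bgcompete::decision_params()) {
  stopifnot(is.finite(coherence), coherence >= 0,
            is.finite(sensory_base), sensory_base >= 0,
            is.finite(sensory_gain), sensory_gain > 0,
            is.finite(cue_strength), cue_strength >= 0,
            inherits(channel_params, "bg_channel_params"),
            inherits(decision_params, "bg_decision_params"))
  if (!(direct_bias > 0.5 && direct_bias <= 1))
    stop("direct_bias must lie in (0.5, 1]")
  if (!(cue_validity >= 0 && cue_validity <= 1))
    stop("cue_validity must lie in [0, 1]")
  structure(list(coherence = coherence, sensory_base = sensory_base,
                 sensory_gain = sensory_gain, direct_bias = direct_bias,
                 cue_strength = cue_strength, cue_validity = cue_validity,
                 channel_params = channel_params,
                 decision_params = decision_params),
            class = "bg_cued_task")
}

# channel inputs for one side given the stimulus and the cue
cued_channel_input <- function(tp, side, stimulus, cue) {
  matched <- as.numeric(side == stimulus)
  s <- tp$sensory_gain * (tp$sensory_base + tp$coherence * matched)
  channel_input(I_d = tp$direct_bias * s,
                I_i = (1 - tp$direct_bias) * s,
                I_m = if (side == cue) tp$cue_strength else 0)
}

#' Run one cued forced-choice trial
#'
#' @param tp A [cued_task_params()] object.
#' @param cue,stimulus `"left"` or `"right"`.
#' @param seed Integer seed for the trial.
#' @return An object of class `bg_cued_result`: list with `cue`,
#'   `stimulus`, `valid`, `response` (`"left"`, `"right"` or `"timeout"`),
#'   `correct` (`NA` on timeout), `rt` (ms, `NA` on timeout) and `seed`.
#' @examples
#' tp <- cued_task_params()
#' run_cued_trial(tp, cue = "right", stimulus = "right", seed = 3)
#' @export
run_cued_trial <- function(tp, cue, stimulus, seed = 1L) {
  stopifnot(inherits(tp, "bg_cued_task"),
            cue %in% c("left", "right"), stimulus %in% c("left", "right"))
  res <- cued_trials_block(tp, cues = cue, stimuli = stimulus,
                           seeds = as.integer(seed))
  structure(as.list(res[1L, ]), class = "bg_cued_result")
}

#' @export
print.bg_cued_result <- function(x, ...) {
  cat(sprintf("<bg_cued_result> cue %s / stimulus %s (%s): response %s%s\n",
              x$cue, x$stimulus, if (x$valid) "valid" else "invalid",
              x$response,
              if (!is.na(x$rt)) sprintf(", rt = %g ms", x$rt) else ""))
  invisible(x)
}

# Vectorized core: n trials with given cue/stimulus/seed vectors.  Each
# trial consumes its own seeded stream: left-channel noise, right-channel
# noise, then one uniform tie-break draw.
cued_trials_block <- function(tp, cues, stimuli, seeds) {
  n <- length(cues)
  p <- tp$channel_params
  dp <- tp$decision_params
  nsteps <- as.integer(ceiling((dp$deadline - dp$t0) / p$dt))
  zero_noise <- p$noise_sd == 0
  epsL_d <- epsL_i <- epsR_d <- epsR_i <- matrix(0, nsteps, n)
  tie_u <- numeric(n)
  for (k in seq_len(n)) {
    set.seed(seeds[k])
    if (!zero_noise) {
      eL <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
      eR <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
      epsL_d[, k] <- eL[, 1L]; epsL_i[, k] <- eL[, 2L]
      epsR_d[, k] <- eR[, 1L]; epsR_i[, k] <- eR[, 2L]
    }
    tie_u[k] <- stats::runif(1L)
  }
  # four input cells: (side matches stimulus?) x (side cued?)
  cross_times <- function(side, eps_d, eps_i) {
    t_cross <- rep(NA_real_, n)
    for (m in c(TRUE, FALSE)) for (cu in c(TRUE, FALSE)) {
      idx <- which((stimuli == side) == m & (cues == side) == cu)
      if (!length(idx)) next
      inp <- channel_input(
        I_d = tp$direct_bias * tp$sensory_gain *
          (tp$sensory_base + tp$coherence * as.numeric(m)),
        I_i = (1 - tp$direct_bias) * tp$sensory_gain *
          (tp$sensory_base + tp$coherence * as.numeric(m)),
        I_m = if (cu) tp$cue_strength else 0)
      res <- integrate_with_evidence(p, inp, dp, nsteps,
                                     list(d = eps_d[, idx, drop = FALSE],
                                          i = eps_i[, idx, drop = FALSE]))
      t_cross[idx] <- res$t_cross
    }
    t_cross
  }
  tL <- cross_times("left", epsL_d, epsL_i)
  tR <- cross_times("right", epsR_d, epsR_i)

  response <- rep("timeout", n)
  rt <- rep(NA_real_, n)
  left_wins <- !is.na(tL) & (is.na(tR) | tL < tR)
  right_wins <- !is.na(tR) & (is.na(tL) | tR < tL)
  tie <- !is.na(tL) & !is.na(tR) & tL == tR
  left_wins[tie] <- tie_u[tie] < 0.5
  right_wins[tie] <- !left_wins[tie]
  response[left_wins] <- "left"
  response[right_wins] <- "right"
  rt[left_wins] <- dp$t0 + tL[left_wins]
  rt[right_wins] <- dp$t0 + tR[right_wins]

  data.frame(cue = cues, stimulus = stimuli,
             valid = cues == stimuli, response = response,
             correct = ifelse(response == "timeout", NA, response == stimuli),
             rt = rt, seed = seeds, stringsAsFactors = FALSE)
}

#' Race two arbitrary channel conditions
#'
#' Low-level two-alternative race: one "correct" and one "error" channel,
#' each with its own input, race to the execution threshold under matched
#' per-trial seeding (correct-channel noise, error-channel noise, then a
#' tie-break uniform).  Used to study how channel-level manipulations
#' (e.g. the `I_d:I_i` ratio) map onto effective diffusion parameters.
#'
#' @param params Shared [channel_params()] object.
#' @param input_correct,input_error [channel_input()] objects for the
#'   channel encoding the correct and the error response.
#' @param dp A [decision_params()] object.
#' @param n Number of trials.
#' @param seed Base seed.
#' @param condition Condition tag.
#' @return A `bg_trials` data frame (kind `"2afc"`) with columns `trial`,
#'   `condition`, `response` (`"correct"`/`"error"`/`"timeout"`),
#'   `correct`, `rt_ms`, `crossed`, `seed`.
#' @export
run_channel_race <- function(params, input_correct, input_error, dp, n,
                             seed = 1L, condition = NA_character_) {
  stopifnot(inherits(params, "bg_channel_params"),
            inherits(input_correct, "bg_channel_input"),
            inherits(input_error, "bg_channel_input"),
            inherits(dp, "bg_decision_params"), n >= 1)
  nsteps <- as.integer(ceiling((dp$deadline - dp$t0) / params$dt))
  epsC_d <- epsC_i <- epsE_d <- epsE_i <- matrix(0, nsteps, n)
  tie_u <- numeric(n)
  seeds <- vapply(seq_len(n) - 1L,
                  function(k) derive_seed(seed, "race-trial", k), integer(1))
  zero_noise <- params$noise_sd == 0
  for (k in seq_len(n)) {
    set.seed(seeds[k])
    if (!zero_noise) {
      eC <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
      eE <- matrix(stats::rnorm(2L * nsteps), nsteps, 2L)
      epsC_d[, k] <- eC[, 1L]; epsC_i[, k] <- eC[, 2L]
      epsE_d[, k] <- eE[, 1L]; epsE_i[, k] <- eE[, 2L]
    }
    tie_u[k] <- stats::runif(1L)
  }
  tC <- integrate_with_evidence(params, input_correct, dp, nsteps,
                                list(d = epsC_d, i = epsC_i))$t_cross
  tE <- integrate_with_evidence(params, input_error, dp, nsteps,
                                list(d = epsE_d, i = epsE_i))$t_cross
  response <- rep("timeout", n)
  rt <- rep(NA_real_, n)
  c_wins <- !is.na(tC) & (is.na(tE) | tC < tE)
  e_wins <- !is.na(tE) & (is.na(tC) | tE < tC)
  tie <- !is.na(tC) & !is.na(tE) & tC == tE
  c_wins[tie] <- tie_u[tie] < 0.5
  e_wins[tie] <- !c_wins[tie]
  response[c_wins] <- "correct"
  response[e_wins] <- "error"
  rt[c_wins] <- dp$t0 + tC[c_wins]
  rt[e_wins] <- dp$t0 + tE[e_wins]
  out <- data.frame(trial = seq_len(n), condition = condition,
                    response = response,
                    correct = ifelse(response == "timeout", NA,
                                     response == "correct"),
                    rt_ms = rt, crossed = response != "timeout",
                    seed = seeds, stringsAsFactors = FALSE)
  new_bg_trials(out,
                params_fingerprint = params_fingerprint(params, input_correct,
                                                        input_error, dp),
                base_seed = as.integer(seed), kind = "2afc")
}

#' Run a block of cued trials
#'
#' Draws stimulus directions uniformly and cues matching the stimulus with
#' probability `cue_validity`, runs all trials, and summarizes accuracy and
#' RT split by cue validity.
#'
#' @param tp A [cued_task_params()] object.
#' @param n Number of trials (>= 1).
#' @param seed Base seed; trial seeds and the cue/stimulus sequence are
#'   derived from it.
#' @return An object of class `bg_cued_block`: list with `trials` (a
#'   `bg_trials` data frame with columns `trial`, `cue`, `stimulus`,
#'   `valid`, `response`, `correct`, `rt_ms`, `seed`) and `by_validity`,
#'   a data frame of per-cell `n`, `accuracy`, `mean_rt`, `sd_rt`,
#'   `timeout_rate` (cells with no trials are absent).
#' @examples
#' blk <- run_cued_block(cued_task_params(), n = 50, seed = 2)
#' blk$by_validity
#' @export
run_cued_block <- function(tp, n, seed = 1L) {
  stopifnot(inherits(tp, "bg_cued_task"), n >= 1)
  set.seed(derive_seed(seed, "cued-sequence"))
  stimuli <- sample(c("left", "right"), n, replace = TRUE)
  valid <- stats::runif(n) < tp$cue_validity
  cues <- ifelse(valid, stimuli, ifelse(stimuli == "left", "right", "left"))
  seeds <- vapply(seq_len(n) - 1L,
                  function(k) derive_seed(seed, "cued-trial", k), integer(1))
  df <- cued_trials_block(tp, cues, stimuli, seeds)
  trials <- data.frame(trial = seq_len(n), cue = df$cue,
                       stimulus = df$stimulus, valid = df$valid,
                       response = df$response, correct = df$correct,
                       rt_ms = df$rt, seed = df$seed,
                       stringsAsFactors = FALSE)
  trials <- new_bg_trials(trials,
                          params_fingerprint = params_fingerprint(tp),
                          base_seed = as.integer(seed), kind = "cued")
  cells <- lapply(split(trials, trials$valid), function(cell) {
    done <- !is.na(cell$correct)
    data.frame(valid = cell$valid[1], n = nrow(cell),
               accuracy = if (any(done)) mean(cell$correct[done]) else NA_real_,
               mean_rt = if (any(done)) mean(cell$rt_ms[done]) else NA_real_,
               sd_rt = if (sum(done) > 1) stats::sd(cell$rt_ms[done]) else NA_real_,
               timeout_rate = mean(!done))
  })
  by_validity <- do.call(rbind, cells)
  rownames(by_validity) <- NULL
  structure(list(trials = trials, by_validity = by_validity),
            class = "bg_cued_block")
}

#' @export
print.bg_cued_block <- function(x, ...) {
  cat(sprintf("<bg_cued_block> %d trials\n", nrow(x$trials)))
  print(x$by_validity, digits = 4)
  invisible(x)
}
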