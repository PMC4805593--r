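#' Specification of a tonic background-drive sweep
#'
#' Tonic dopamine availability is modelled as the strength of the
#' non-specific background drive `I_lambda`.  A sweep runs the same
#' go/no-go condition (fixed `I_d:I_i`, here carried by a network with
#' stronger direct- than indirect-pathway weighting) at each level and
#' quantifies speed, variability and exploration.
#'
#' @param levels Strictly increasing `I_lambda` values.
#' @param n_per_level Trials per level (>= 1).
#' @param params Channel parameter template (the default preset weights
#'   cortical input more strongly to the direct pathway and routes the
#'   non-selective drives through the pathway gains).
#' @param input Channel input template; its `I_lambda` field is replaced
#'   per level.
#' @param decision_params A [decision_params()] object.
#' @param learning_params A [learning_params()] object for the paired
#'   exploration probe (see Details).
#' @param probe_q_diff Fixed value difference used in the exploration
#'   probe, a two-alternative race run at each level whose response
#'   entropy indexes exploration.
#' @param n_probe Trials in the exploration probe per level.
#' @param seed Base seed.
#' @return An object of class `bg_sweep_spec`.
#' @export
sweep_spec <- function(levels = c(0, 0.15, 0.3), n_per_level = 1000,
                       params = tonic_preset()$params,
                       input = tonic_preset()$input,
                       decision_params = bgcompete::decision_params(),
                       learning_params = bgcompete::learning_params(),
                       probe_q_diff = 0.5, n_probe = 8000, seed = 1L) {
  stopifnot(length(levels) >= 1, all(diff(levels) > 0), all(levels >= 0),
            n_per_level >= 1, n_probe >= 0,
            inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"),
            inherits(decision_params, "bg_decision_params"),
            inherits(learning_params, "bg_learning_params"),
            probe_q_diff >= 0, probe_q_diff <= 1)
  structure(list(levels = levels, n_per_level = as.integer(n_per_level),
                 params = params, input = input,
                 decision_params = decision_params,
                 learning_params = learning_params,
                 probe_q_diff = probe_q_diff, n_probe = as.integer(n_probe),
                 seed = as.integer(seed)),
            class = "bg_sweep_spec")
}

#' Channel preset for tonic-dopamine sweeps
#'
#' A go/no-go channel in which cortical input is weighted more strongly
#' toward the direct than the indirect pathway (`g_d > g_i`) and the
#' non-selective drives pass through those same gains (`ns_weighted`),
#' reflecting the opposite sensitivities of the two striatal populations
#' to dopamine.  Raising `I_lambda` in this network speeds gating,
#' tightens the RT distribution and biases the outcome toward "go".
#'
#' @return list with elements `params` and `input`.
#' @export
tonic_preset <- function() {
  list(params = channel_params(tau = 100, w_self = 1.5, w_inh = 1.5,
                               g_d = 1.15, g_i = 0.85,
                               activation = activation_logistic(slope = 4,
                                                                offset = 1,
                                                                r_max = 1),
                               noise_sd = 0.02, dt = 1, ceiling = 10,
                               ns_weighted = TRUE),
       input = channel_input(I_d = 0.55, I_i = 0.55))
}

#' Sweep tonic background drive
#'
#' For each `I_lambda` level, runs `n_per_level` go/no-go trials through
#' the network and decision readout, plus an exploration probe: a
#' two-alternative race at a fixed value difference whose drifts are
#' scaled by the same tonic level (higher tonic drive means more
#' exploitation, i.e. lower response entropy).  The sweep never alters any
#' learning state: tonic modulation changes expression, not learning.
#'
#' @param spec A [sweep_spec()] object.
#' @return An object of class `bg_sweep`: data frame with one row per
#'   level and columns `level`, `I_lambda`, `go_rate`, `mean_rt_ms`,
#'   `sd_rt_ms`, `rt_q10` ... `rt_q90`, `entropy_bits`,
#'   `gate_time_median_ms`; the per-level trial sets are kept in the
#'   `trial_sets` attribute.
#' @examples
#' sw <- run_tonic_sweep(sweep_spec(n_per_level = 50, n_probe = 50))
#' sw
#' @export
run_tonic_sweep <- function(spec) {
  stopifnot(inherits(spec, "bg_sweep_spec"))
  rows <- list()
  sets <- list()
  for (k in seq_along(spec$levels)) {
    lam <- spec$levels[k]
    inp <- spec$input
    inp$I_lambda <- lam
    seed_k <- derive_seed(spec$seed, "sweep-level", k - 1L)
    ts <- run_trials(spec$params, inp, spec$decision_params,
                     n = spec$n_per_level, seed = seed_k,
                     condition = sprintf("I_lambda=%g", lam))
    s <- summary(ts)
    # exploration probe: response entropy of the value race at this level
    ent <- NA_real_
    if (spec$n_probe > 0) {
      st <- learning_state()
      st$q_opt <- 0.5 + spec$probe_q_diff / 2
      st$q_sub <- 0.5 - spec$probe_q_diff / 2
      drifts <- drift_rates(st, spec$learning_params)
      set.seed(derive_seed(spec$seed, "sweep-probe", k - 1L))
      probe <- vapply(seq_len(spec$n_probe), function(j)
        race_trial(drifts, spec$learning_params,
                   lambda_scale = 1 + spec$learning_params$lambda_gain * lam)$choice,
        character(1))
      ent <- choice_entropy(probe)
    }
    # median gate time from a subsample of full trajectories
    n_gate <- min(100L, spec$n_per_level)
    gates <- vapply(seq_len(n_gate), function(j) {
      tr <- simulate_channel(spec$params, inp,
                             horizon = spec$decision_params$deadline -
                               spec$decision_params$t0,
                             seed = derive_seed(seed_k, "trial-noise", j - 1L))
      gate_time(tr, separation = 0.2, dwell = 50)
    }, numeric(1))
    rows[[k]] <- data.frame(
      level = k, I_lambda = lam,
      go_rate = s$go_rate, mean_rt_ms = s$mean_rt, sd_rt_ms = s$sd_rt,
      rt_q10 = s$rt_quantiles[[1]], rt_q30 = s$rt_quantiles[[2]],
      rt_q50 = s$rt_quantiles[[3]], rt_q70 = s$rt_quantiles[[4]],
      rt_q90 = s$rt_quantiles[[5]],
      entropy_bits = ent,
      gate_time_median_ms = stats::median(gates, na.rm = TRUE))
    sets[[k]] <- ts
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, trial_sets = sets, spec = spec,
            class = c("bg_sweep", "data.frame"))
}

#' @export
print.bg_sweep <- function(x, ...) {
  cat(sprintf("<bg_sweep> %d tonic levels x %d trials\n",
              nrow(x), attr(x, "spec")$n_per_level))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Shannon entropy of a response distribution
#'
#' Entropy in bits of the empirical distribution of responses, with the
#' convention `0 * log(0) = 0`.  Used as the operational measure of
#' exploration: a fully stereotyped responder scores 0 bits, a uniform
#' responder over two options scores 1 bit.
#'
#' @param responses A character/factor vector of responses, or a
#'   `bg_trials` data frame (its `label` or `response` column is used).
#' @return Entropy in bits.
#' @export
choice_entropy <- function(responses) {
  if (is.data.frame(responses)) {
    col <- intersect(c("response", "label", "choice"), names(responses))[1]
    if (is.na(col)) stop("no response column found")
    responses <- responses[[col]]
  }
  responses <- responses[!is.na(responses)]
  if (length(responses) == 0L) stop("cannot compute entropy of an empty set")
  p <- table(responses) / length(responses)
  p <- p[p > 0]
  -sum(p * log2(p))
}
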