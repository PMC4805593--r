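#' Default run configuration
#'
#' One nested list holding every tunable parameter of every module, keyed
#' by module name.  [load_config()] fills unspecified keys from these
#' defaults and rejects unknown keys.
#'
#' @return A named list with components `network`, `input`, `decision`,
#'   `cued`, `learning`, `sweep`, plus top-level `seed`, `output_dir` and
#'   `log_level`.
#' @export
default_config <- function() {
  list(
    network = list(tau = 100, w_self = 1.5, w_inh = 1.5, g_d = 1, g_i = 1,
                   activation = list(kind = "logistic", slope = 4,
                                     offset = 1, r_max = 1),
                   noise_sd = 0.02, dt = 1, ceiling = 10,
                   ns_weighted = FALSE, lambda_mode = "additive"),
    input = list(I_d = 0.55, I_i = 0.35, I_m = 0, I_lambda = 0),
    decision = list(threshold = 1, deadline = 1500, evidence_gain = 0.005,
                    norm_eps = 1e-3, t0 = 100, baseline = 0),
    cued = list(coherence = 0.3, sensory_base = 1, sensory_gain = 0.9,
                direct_bias = 0.65, cue_strength = 0.15, cue_validity = 0.8),
    learning = list(alpha_q = 0.05, delta = 0.01, drift_map_slope = 0.004,
                    drift_base = 0.0022, gain_bounds = c(0.25, 1.75),
                    boundary = 1, race_noise_sd = 0.045, deadline = 1500,
                    t0 = 100, rpe_scaled = FALSE, lambda_gain = 1,
                    p_opt = 0.8, p_sub = 0.2, n_trials = 200),
    sweep = list(levels = c(0, 0.15, 0.3), n_per_level = 1000,
                 probe_q_diff = 0.5, n_probe = 8000),
    seed = 1L,
    output_dir = ".",
    log_level = "info"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills every unspecified key from
#' [default_config()], rejects unknown keys, and validates every value by
#' constructing the corresponding parameter objects (so a violated
#' invariant fails here, naming the offending constraint, before any
#' simulation starts).  An empty or absent-body file yields the default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list of class `bg_config`, with the
#'   realized parameter objects in attribute `objects`.
#' @seealso [save_config()] for the inverse; load -> save -> load is the
#'   identity on the configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_config(user)
}

#' @rdname load_config
#' @param config A configuration list (possibly partial).
#' @export
as_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  for (sec in names(config)) {
    if (is.list(defaults[[sec]]) && !is.null(names(defaults[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad))
        stop("unknown key(s) in section '", sec, "': ",
             paste(bad, collapse = ", "))
      for (k in names(config[[sec]])) merged[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      merged[[sec]] <- config[[sec]]
    }
  }
  if (!merged$log_level %in% c("debug", "info", "warning"))
    stop("log_level must be one of debug, info, warning")
  merged$seed <- as.integer(merged$seed)
  objects <- realize_config(merged)
  structure(merged, objects = objects, class = c("bg_config", "list"))
}

# construct every parameter object, so all invariants are checked up front
realize_config <- function(cfg) {
  nw <- cfg$network
  params <- channel_params(tau = nw$tau, w_self = nw$w_self, w_inh = nw$w_inh,
                           g_d = nw$g_d, g_i = nw$g_i,
                           activation = as_activation(nw$activation),
                           noise_sd = nw$noise_sd, dt = nw$dt,
                           ceiling = nw$ceiling, ns_weighted = nw$ns_weighted,
                           lambda_mode = nw$lambda_mode)
  input <- do.call(channel_input, cfg$input)
  dp <- do.call(decision_params, cfg$decision)
  lrn <- cfg$learning
  lp <- learning_params(alpha_q = lrn$alpha_q, delta = lrn$delta,
                        drift_map_slope = lrn$drift_map_slope,
                        drift_base = lrn$drift_base,
                        gain_bounds = as.numeric(lrn$gain_bounds),
                        boundary = lrn$boundary,
                        race_noise_sd = lrn$race_noise_sd,
                        deadline = lrn$deadline, t0 = lrn$t0,
                        rpe_scaled = lrn$rpe_scaled,
                        lambda_gain = lrn$lambda_gain)
  rs <- reward_schedule(lrn$p_opt, lrn$p_sub, lrn$n_trials)
  tp <- cued_task_params(coherence = cfg$cued$coherence,
                         sensory_base = cfg$cued$sensory_base,
                         sensory_gain = cfg$cued$sensory_gain,
                         direct_bias = cfg$cued$direct_bias,
                         cue_strength = cfg$cued$cue_strength,
                         cue_validity = cfg$cued$cue_validity,
                         channel_params = params, decision_params = dp)
  sw <- sweep_spec(levels = as.numeric(cfg$sweep$levels),
                   n_per_level = cfg$sweep$n_per_level,
                   params = params, input = input, decision_params = dp,
                   learning_params = lp,
                   probe_q_diff = cfg$sweep$probe_q_diff,
                   n_probe = cfg$sweep$n_probe, seed = cfg$seed)
  list(params = params, input = input, decision = dp, learning = lp,
       schedule = rs, cued = tp, sweep = sw)
}

#' @rdname load_config
#' @param path Destination file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "bg_config") || is.list(config))
  plain <- unclass(config)
  attr(plain, "objects") <- NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @export
print.bg_config <- function(x, ...) {
  cat("<bg_config>\n")
  cat(yaml::as.yaml(local({p <- unclass(x); attr(p, "objects") <- NULL; p})))
  invisible(x)
}
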