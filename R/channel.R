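#' Dynamical constants of one action channel
#'
#' One action channel is modelled as two competing rate populations — the
#' direct (motor-facilitating, "Believer") and indirect (motor-suppressing,
#' "Skeptic") pathways — with recurrent self-excitation within each
#' population and mutual inhibition between them.  Both populations obey
#'
#' \deqn{\tau \, \dot{x} = -x + f(w_{self} x - w_{inh} y +
#'       g \, I_{sel} + I_m + I_\lambda) + \sigma \sqrt{dt}\, \xi}
#'
#' where `x`/`y` are the population's own and the opposing rate, `f` the
#' transfer function, `g` the pathway-specific input sensitivity
#' (`g_d` for the direct, `g_i` for the indirect population),
#' `I_sel` its selective drive, and `I_m`, `I_lambda` the non-selective
#' drives shared by both populations (entering unweighted by default).
#' States are rectified at zero after each Euler-Maruyama step.
#'
#' @param tau Membrane/population time constant, ms.
#' @param w_self Recurrent self-excitation weight (>= 0).
#' @param w_inh Cross-inhibition weight (>= 0).
#' @param g_d,g_i Input sensitivities of the direct and indirect
#'   populations (> 0); these are the cortico-striatal weights that
#'   reinforcement feedback re-tunes.
#' @param activation A [bg_activation][activation] object.
#' @param noise_sd Standard deviation of the additive per-step Gaussian
#'   noise (rate units; scaled by `sqrt(dt)`).
#' @param dt Integration step, ms.  Must satisfy `dt <= tau / 10`.
#' @param ceiling Activity level treated as divergence; integration stops
#'   with an instability error if either rate exceeds it.
#' @param ns_weighted If `TRUE`, the non-selective drives `I_m` and
#'   `I_lambda` pass through the pathway gains `g_d`/`g_i` like the
#'   selective inputs; by default they enter unweighted.
#' @param lambda_mode How the tonic drive `I_lambda` interacts with the
#'   rest of the input: `"additive"` (default) adds it to the net input;
#'   `"gain"` multiplies the summed input by `1 + I_lambda` instead.
#' @return An object of class `bg_channel_params`.
#' @seealso [channel_input()], [simulate_channel()], [channel_preset()]
#' @export
channel_params <- function(tau = 100, w_self = 0.7, w_inh = 1.2,
                           g_d = 1, g_i = 1,
                           activation = activation_threshold_linear(),
                           noise_sd = 0, dt = 1, ceiling = 10,
                           ns_weighted = FALSE,
                           lambda_mode = c("additive", "gain")) {
  lambda_mode <- match.arg(lambda_mode)
  activation <- as_activation(activation)
  stopifnot(is.finite(tau), tau > 0,
            is.finite(dt), dt > 0,
            is.finite(w_self), w_self >= 0,
            is.finite(w_inh), w_inh >= 0,
            is.finite(g_d), g_d > 0,
            is.finite(g_i), g_i > 0,
            is.finite(noise_sd), noise_sd >= 0,
            is.finite(ceiling), ceiling > 0)
  if (dt > tau / 10)
    stop("integration step too coarse: dt must satisfy dt <= tau/10 (dt = ",
         dt, ", tau = ", tau, ")")
  stopifnot(is.logical(ns_weighted), length(ns_weighted) == 1L)
  structure(list(tau = tau, w_self = w_self, w_inh = w_inh,
                 g_d = g_d, g_i = g_i, activation = activation,
                 noise_sd = noise_sd, dt = dt, ceiling = ceiling,
                 ns_weighted = ns_weighted, lambda_mode = lambda_mode),
            class = "bg_channel_params")
}

#' Drive terms of one action channel
#'
#' The four input components of a channel: selective drive to the direct
#' (`I_d`) and indirect (`I_i`) populations, a modulatory non-selective
#' drive (`I_m`, e.g. cued-expectation priming) and a tonic non-specific
#' background drive (`I_lambda`, the tonic-dopamine analogue).  `I_m` and
#' `I_lambda` reach both populations identically and, by default, enter
#' unweighted by the pathway gains.
#'
#' @param I_d,I_i Selective drives (>= 0).
#' @param I_m Modulatory non-selective drive (>= 0).
#' @param I_lambda Tonic background drive (>= 0).
#' @return An object of class `bg_channel_input`.
#' @export
channel_input <- function(I_d = 0, I_i = 0, I_m = 0, I_lambda = 0) {
  vals <- c(I_d = I_d, I_i = I_i, I_m = I_m, I_lambda = I_lambda)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all input components must be finite and >= 0")
  structure(as.list(vals), class = "bg_channel_input")
}

#' Documented channel parameter presets
#'
#' Named parameter/input bundles used throughout the package's examples and
#' tests:
#'
#' * `"leak"` — threshold-linear, leak-dominated (`w_self < 1`, no input):
#'   a single stable equilibrium at the origin.  Baseline for linear-regime
#'   analyses.
#' * `"bistable"` — logistic transfer with strong self-excitation
#'   (`w_self = w_inh = 1.5`, slope 4): under symmetric drive the network
#'   has two stable attractors (Go-like: direct wins; NoGo-like: indirect
#'   wins) separated by a symmetric saddle, and small noise selects one.
#' * `"gonogo"` — the `"bistable"` dynamics plus a moderate symmetric drive
#'   and noise; the default condition for go/no-go trials in which the
#'   `I_d:I_i` ratio controls speed and go-rate.
#'
#' @param name Preset name.
#' @return A list with elements `params` (`bg_channel_params`) and
#'   `input` (`bg_channel_input`).
#' @export
channel_preset <- function(name = c("gonogo", "bistable", "leak")) {
  name <- match.arg(name)
  switch(name,
    leak = list(
      params = channel_params(tau = 100, w_self = 0.5, w_inh = 1,
                              activation = activation_threshold_linear(),
                              noise_sd = 0, dt = 1),
      input = channel_input()
    ),
    bistable = list(
      params = channel_params(tau = 100, w_self = 1.5, w_inh = 1.5,
                              g_d = 1, g_i = 1,
                              activation = activation_logistic(slope = 4,
                                                               offset = 1,
                                                               r_max = 1),
                              noise_sd = 0.02, dt = 1, ceiling = 10),
      input = channel_input(I_d = 0.45, I_i = 0.45)
    ),
    gonogo = list(
      params = channel_params(tau = 100, w_self = 1.5, w_inh = 1.5,
                              g_d = 1, g_i = 1,
                              activation = activation_logistic(slope = 4,
                                                               offset = 1,
                                                               r_max = 1),
                              noise_sd = 0.02, dt = 1, ceiling = 10),
      input = channel_input(I_d = 0.45, I_i = 0.45)
    )
  )
}

#' @export
print.bg_channel_params <- function(x, ...) {
  cat("<bg_channel_params>\n")
  cat(sprintf("  tau = %g ms, dt = %g ms, ceiling = %g\n", x$tau, x$dt, x$ceiling))
  cat(sprintf("  w_self = %g, w_inh = %g, g_d = %g, g_i = %g\n",
              x$w_self, x$w_inh, x$g_d, x$g_i))
  cat(sprintf("  activation: %s (slope %g, offset %g%s)\n", x$activation$kind,
              x$activation$slope, x$activation$offset,
              if (!is.null(x$activation$r_max))
                paste0(", r_max ", x$activation$r_max) else ""))
  cat(sprintf("  noise_sd = %g\n", x$noise_sd))
  invisible(x)
}

#' @export
print.bg_channel_input <- function(x, ...) {
  cat(sprintf("<bg_channel_input> I_d = %g, I_i = %g, I_m = %g, I_lambda = %g\n",
              x$I_d, x$I_i, x$I_m, x$I_lambda))
  invisible(x)
}

# split a total selective drive S into (I_d, I_i) with ratio r = I_d / I_i
split_ratio <- function(total, ratio) {
  stopifnot(total >= 0, ratio > 0)
  c(I_d = total * ratio / (1 + ratio), I_i = total / (1 + ratio))
}
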