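#' Transfer functions for the rate populations
#'
#' The population transfer function maps net synaptic input to steady-state
#' firing rate.  Two forms are supported:
#'
#' * **threshold-linear** (default): `f(u) = slope * max(u - offset, 0)`.
#'   Unbounded above; suitable for leak-dominated analyses where the linear
#'   regime is the object of study.
#' * **logistic**: `f(u) = r_max / (1 + exp(-slope * (u - offset)))`.
#'   Saturating; its input-dependent gain `f'(u)` is what lets non-selective
#'   background drive change the stability of the symmetric network state
#'   (the baseline-excitability mechanism behind cue priming and tonic
#'   modulation).
#'
#' @param slope Gain parameter (threshold-linear: linear slope; logistic:
#'   steepness at the inflection point is `slope * r_max / 4`).
#' @param offset Input at which the function turns on (threshold-linear) or
#'   reaches half its maximum (logistic).
#' @param r_max Saturation rate of the logistic form (rate units).
#' @return An object of class `bg_activation`: a list with elements `kind`,
#'   `slope`, `offset` and, for the logistic form, `r_max`.
#' @examples
#' f <- activation_logistic(slope = 4, offset = 1)
#' act_eval(f, c(0, 1, 2))
#' @name activation
NULL

#' @rdname activation
#' @export
activation_threshold_linear <- function(slope = 1, offset = 0) {
  stopifnot(is.finite(slope), slope > 0, is.finite(offset))
  structure(list(kind = "threshold_linear", slope = slope, offset = offset),
            class = "bg_activation")
}

#' @rdname activation
#' @export
activation_logistic <- function(slope = 4, offset = 1, r_max = 1) {
  stopifnot(is.finite(slope), slope > 0, is.finite(offset),
            is.finite(r_max), r_max > 0)
  structure(list(kind = "logistic", slope = slope, offset = offset,
                 r_max = r_max),
            class = "bg_activation")
}

#' @rdname activation
#' @param act A `bg_activation` object.
#' @param u Net input (vectorized).
#' @export
act_eval <- function(act, u) {
  switch(act$kind,
    threshold_linear = act$slope * pmax(u - act$offset, 0),
    logistic = act$r_max / (1 + exp(-act$slope * (u - act$offset))),
    stop("unknown activation kind: ", act$kind)
  )
}

# derivative f'(u), used by the fixed-point Jacobian
act_deriv <- function(act, u) {
  switch(act$kind,
    threshold_linear = act$slope * as.numeric(u > act$offset),
    logistic = {
      f <- act_eval(act, u)
      act$slope * f * (1 - f / act$r_max)
    },
    stop("unknown activation kind: ", act$kind)
  )
}

as_activation <- function(x) {
  if (inherits(x, "bg_activation")) return(x)
  stopifnot(is.list(x), !is.null(x$kind))
  kind <- gsub("-", "_", x$kind)
  if (kind == "threshold_linear") {
    activation_threshold_linear(slope = x$slope %||% 1, offset = x$offset %||% 0)
  } else if (kind == "logistic") {
    activation_logistic(slope = x$slope %||% 4, offset = x$offset %||% 1,
                        r_max = x$r_max %||% 1)
  } else stop("unknown activation kind: ", x$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
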