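#' Simulate two-boundary drift-diffusion trials
#'
#' Euler-Maruyama simulation of the constant-drift diffusion
#' `dX = v dt + s dW` started midway between absorbing boundaries at 0 and
#' `a`; an upper crossing is a correct response, a lower crossing an
#' error.  Used as the synthetic generator for parameter-recovery checks
#' of [estimate_ddm()].
#'
#' @param v Drift rate (evidence/s).
#' @param a Boundary separation (evidence units).
#' @param t0 Non-decision time (s).
#' @param n Number of trials.
#' @param s Diffusion coefficient (evidence/sqrt(s)); the scaling
#'   convention the estimates are expressed in.
#' @param dt Integration step (s).
#' @param max_t Simulation cutoff (s); trials that never cross are dropped.
#' @param seed Integer seed.
#' @return A `bg_trials` data frame (kind `"2afc"`) with columns `trial`,
#'   `condition`, `response` (`"upper"`/`"lower"`), `correct`, `rt_ms`,
#'   `crossed`, `seed`.
#' @export
simulate_diffusion <- function(v, a, t0, n, s = 1, dt = 1e-3,
                               max_t = 10, seed = 1L) {
  stopifnot(a > 0, t0 >= 0, n >= 1, s > 0, dt > 0)
  set.seed(seed)
  nmax <- ceiling(max_t / dt)
  x <- rep(a / 2, n)
  done <- logical(n)
  hit_upper <- logical(n)
  t_hit <- rep(NA_real_, n)
  sdt <- s * sqrt(dt)
  for (k in seq_len(nmax)) {
    act <- which(!done)
    if (!length(act)) break
    x[act] <- x[act] + v * dt + sdt * stats::rnorm(length(act))
    up <- act[x[act] >= a]
    lo <- act[x[act] <= 0]
    done[c(up, lo)] <- TRUE
    hit_upper[up] <- TRUE
    t_hit[c(up, lo)] <- k * dt
  }
  keep <- done
  out <- data.frame(
    trial = seq_len(sum(keep)),
    condition = sprintf("ddm v=%g a=%g", v, a),
    response = ifelse(hit_upper[keep], "upper", "lower"),
    correct = hit_upper[keep],
    rt_ms = (t0 + t_hit[keep]) * 1000,
    crossed = TRUE,
    seed = as.integer(seed),
    stringsAsFactors = FALSE)
  new_bg_trials(out, params_fingerprint = params_fingerprint(v, a, t0, s),
                base_seed = as.integer(seed), kind = "2afc")
}

#' Moment-based drift-diffusion parameter recovery
#'
#' Closed-form inversion of the two-boundary constant-drift diffusion from
#' three summary statistics — accuracy, and the mean and variance of
#' correct-response RTs — in the tradition of the EZ-diffusion equations.
#' Given accuracy `Pc` (edge-corrected to `1/(2n)` or `1 - 1/(2n)` when it
#' is exactly 0 or 1) and logit `L = log(Pc / (1 - Pc))`:
#' \deqn{v = sign(P_c - 1/2)\, s \left( \frac{L (P_c^2 L - P_c L + P_c -
#'   1/2)}{VRT} \right)^{1/4}, \qquad a = \frac{s^2 L}{v},}
#' and `t0 = MRT - (a / 2v) (1 - e^{-va/s^2}) / (1 + e^{-va/s^2})`.
#' The estimator is deterministic given the trial set and invariant to
#' trial order.  RTs are converted ms to s at this boundary only.
#'
#' @param ts A two-alternative `bg_trials` data frame with logical
#'   `correct` and `rt_ms` columns (timeouts are dropped), or a list
#'   with elements `correct` and `rt_ms`.
#' @param s Diffusion coefficient fixing the scaling convention.
#' @param min_n Minimum number of completed trials required.
#' @return An object of class `bg_ddm_params`: list with `drift`
#'   (evidence/s), `boundary`, `t0` (s), `accuracy`, `n`.
#' @examples
#' ts <- simulate_diffusion(v = 1.5, a = 1.2, t0 = 0.25, n = 2000, seed = 8)
#' estimate_ddm(ts)
#' @export
estimate_ddm <- function(ts, s = 1, min_n = 100L) {
  correct <- ts$correct
  rt_s <- ts$rt_ms / 1000
  ok <- !is.na(correct) & !is.na(rt_s)
  correct <- correct[ok]
  rt_s <- rt_s[ok]
  n <- length(correct)
  if (n < min_n)
    stop("estimate_ddm needs at least ", min_n, " completed trials (got ",
         n, ")")
  pc <- mean(correct)
  if (pc <= 0) pc <- 1 / (2 * n)
  if (pc >= 1) pc <- 1 - 1 / (2 * n)
  mrt <- mean(rt_s[correct])
  vrt <- stats::var(rt_s[correct])
  if (pc == 0.5 || is.na(vrt) || vrt <= 0) {
    # symmetric or degenerate case: the logit vanishes and boundary /
    # non-decision time are unidentified by these moments
    v <- 0
    a <- NA_real_
    t0 <- NA_real_
  } else {
    L <- stats::qlogis(pc)
    x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
    v <- sign(pc - 0.5) * s * x^(1 / 4)
    a <- s^2 * L / v
    y <- -v * a / s^2
    mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
    t0 <- mrt - mdt
  }
  structure(list(drift = v, boundary = a, t0 = t0, accuracy = pc, n = n),
            class = "bg_ddm_params")
}

#' @export
print.bg_ddm_params <- function(x, ...) {
  cat(sprintf(paste0("<bg_ddm_params> drift = %.4f /s, boundary = %.4f, ",
                     "t0 = %.4f s (accuracy %.3f, n = %d)\n"),
              x$drift, x$boundary, x$t0, x$accuracy, x$n))
  invisible(x)
}

#' Bootstrap comparison of effective diffusion parameters
#'
#' Estimates the per-parameter difference (`a - b`) between two trial
#' sets with trial-level nonparametric bootstrap percentile intervals.
#'
#' @param a,b Two-alternative trial sets satisfying the [estimate_ddm()]
#'   preconditions.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param s Diffusion coefficient passed to [estimate_ddm()].
#' @return A data frame with rows `drift`, `boundary`, `t0` and columns
#'   `estimate` (difference of point estimates), `lower`, `upper`.
#' @export
compare_conditions <- function(a, b, n_boot = 1000, seed = 1L,
                               level = 0.95, s = 1) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  pa <- estimate_ddm(a, s = s)
  pb <- estimate_ddm(b, s = s)
  boot_one <- function(ts) {
    done <- ts[!is.na(ts$correct) & !is.na(ts$rt_ms), , drop = FALSE]
    n <- nrow(done)
    out <- matrix(NA_real_, n_boot, 3)
    for (bidx in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- estimate_ddm(list(correct = done$correct[idx],
                               rt_ms = done$rt_ms[idx]), s = s)
      out[bidx, ] <- c(est$drift, est$boundary, est$t0)
    }
    out
  }
  set.seed(derive_seed(seed, "boot-a"))
  ba <- boot_one(a)
  set.seed(derive_seed(seed, "boot-b"))
  bb <- boot_one(b)
  diffs <- ba - bb
  alpha <- (1 - level) / 2
  ci <- apply(diffs, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(parameter = c("drift", "boundary", "t0"),
             estimate = c(pa$drift - pb$drift,
                          pa$boundary - pb$boundary,
                          pa$t0 - pb$t0),
             lower = ci[1, ], upper = ci[2, ],
             row.names = NULL)
}
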