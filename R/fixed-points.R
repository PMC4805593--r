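#' Equilibria of the noise-free channel dynamics
#'
#' Finds the fixed points of the deterministic (zero-noise) two-population
#' dynamics on a search grid over `[0, ceiling]^2`, polishing each candidate
#' by damped Newton iteration on the residual
#' `F(d, i) = (-d + f(u_d), -i + f(u_i))` and classifying stability from
#' the eigenvalues of the analytic 2x2 Jacobian.  With strong recurrent
#' self-excitation and symmetric drive the network is bistable: a Go-like
#' attractor (direct pathway wins), a NoGo-like attractor (indirect wins),
#' and a symmetric saddle between them.
#'
#' @inheritParams step_channel
#' @param grid_n Number of grid points per axis for the initial candidates.
#' @param tol Residual norm below which a candidate counts as converged.
#' @param merge_tol Distance (rate units) under which equilibria are merged.
#' @param max_iter Newton iteration cap per candidate.
#' @return An object of class `bg_fixed_points`: a data frame with columns
#'   `d`, `i`, `stability` (`"stable"`, `"saddle"` or `"unstable"`) and the
#'   two Jacobian eigenvalue real parts `re1`, `re2`; non-converged
#'   candidates are dropped (their count is kept in attribute
#'   `n_nonconverged`).
#' @examples
#' pre <- channel_preset("bistable")
#' find_fixed_points(pre$params, pre$input)
#' @export
find_fixed_points <- function(params, input, grid_n = 15, tol = 1e-9,
                              merge_tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(params, "bg_channel_params"),
            inherits(input, "bg_channel_input"))
  drive <- net_drive(params, input)
  f <- params$activation
  gain <- drive$gain

  resid <- function(x) {
    u_d <- (params$w_self * x[1] - params$w_inh * x[2] + drive$d) * gain
    u_i <- (params$w_self * x[2] - params$w_inh * x[1] + drive$i) * gain
    c(-x[1] + act_eval(f, u_d), -x[2] + act_eval(f, u_i))
  }
  jac <- function(x) {
    u_d <- (params$w_self * x[1] - params$w_inh * x[2] + drive$d) * gain
    u_i <- (params$w_self * x[2] - params$w_inh * x[1] + drive$i) * gain
    fd <- act_deriv(f, u_d) * gain
    fi <- act_deriv(f, u_i) * gain
    matrix(c(-1 + fd * params$w_self, -fd * params$w_inh,
             -fi * params$w_inh,      -1 + fi * params$w_self),
           2, 2, byrow = TRUE)
  }

  hi <- if (f$kind == "logistic") min(params$ceiling, 1.5 * f$r_max) else params$ceiling
  grid <- seq(0, hi, length.out = grid_n)
  cands <- as.matrix(expand.grid(d = grid, i = grid))
  found <- list()
  n_fail <- 0L
  for (k in seq_len(nrow(cands))) {
    x <- cands[k, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      r <- resid(x)
      if (sqrt(sum(r^2)) < tol) { ok <- TRUE; break }
      J <- jac(x)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      # damped update, kept inside the admissible quadrant
      lambda <- 1
      repeat {
        xn <- pmax(x + lambda * step, 0)
        if (sqrt(sum(resid(xn)^2)) < sqrt(sum(r^2)) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      if (sqrt(sum(abs(xn - x)^2)) < 1e-14 && sqrt(sum(resid(xn)^2)) >= tol) break
      x <- xn
    }
    if (!ok) { n_fail <- n_fail + 1L; next }
    if (any(x < -merge_tol) || any(x > params$ceiling + merge_tol)) next
    dup <- any(vapply(found, function(p) sqrt(sum((p - x)^2)) < merge_tol,
                      logical(1)))
    if (!dup) found[[length(found) + 1L]] <- x
  }

  if (length(found) == 0L) {
    out <- data.frame(d = numeric(0), i = numeric(0),
                      stability = character(0),
                      re1 = numeric(0), re2 = numeric(0))
  } else {
    pts <- do.call(rbind, found)
    eigs <- t(apply(pts, 1L, function(x) {
      ev <- eigen(jac(x), only.values = TRUE)$values
      sort(Re(ev))
    }))
    stab <- ifelse(eigs[, 2] < 0, "stable",
                   ifelse(eigs[, 1] < 0, "saddle", "unstable"))
    out <- data.frame(d = pts[, 1], i = pts[, 2], stability = stab,
                      re1 = eigs[, 1] / params$tau, re2 = eigs[, 2] / params$tau)
    out <- out[order(out$d, out$i), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_nonconverged") <- n_fail
  class(out) <- c("bg_fixed_points", "data.frame")
  out
}

#' @export
print.bg_fixed_points <- function(x, ...) {
  cat(sprintf("<bg_fixed_points> %d equilibria (%d stable, %d saddle, %d unstable)\n",
              nrow(x), sum(x$stability == "stable"),
              sum(x$stability == "saddle"), sum(x$stability == "unstable")))
  print.data.frame(x, digits = 5)
  invisible(x)
}
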