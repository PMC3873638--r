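# Node-resolved dimensionless parameters from a beta_grid: each returned
# vector has one entry per node, falling back to the homogeneous value in p.
grid_params <- function(p, grid) {
  if (is.null(grid)) {
    list(I = p$I, g = p$g, w_jump = p$w_jump, a = p$a, weight = 1)
  } else {
    M <- nrow(grid)
    list(I = if ("I" %in% names(grid)) grid$I else rep(p$I, M),
         g = if ("g" %in% names(grid)) grid$g else rep(p$g, M),
         w_jump = if ("w_jump" %in% names(grid)) grid$w_jump else
           rep(p$w_jump, M),
         a = if ("tau_w" %in% names(grid)) 1 / grid$tau_w else rep(p$a, M),
         weight = grid$weight)
  }
}

#' Right-hand side of the homogeneous mean-field reduction (MFI)
#'
#' The two switching ODEs for the mean adaptation and the gating variable,
#' with the firing rate and mean voltage evaluated at the mean parameters:
#' `w' = a (b <v> - w) + w_jump R`, `s' = -s/tau_s + s_jump R`.
#'
#' @param state numeric `c(w, s)`.
#' @param p an `izh_params_nd`.
#' @return Numeric derivative vector of length 2.
#' @export
mfi_rhs <- function(state, p) {
  R <- firing_rate_izh(state[1], state[2], p)
  vb <- if (p$b != 0) mean_v_izh(state[1], state[2], p) else 0
  c(p$a * (p$b * vb - state[1]) + p$w_jump * R,
    -state[2] / p$tau_s + p$s_jump * R)
}

#' Right-hand side of the parameter-resolved mean-field reduction (MFII)
#'
#' Same two-dimensional skeleton as MFI, but the firing rate and mean
#' voltage are integrals of the parameter-conditioned quantities over the
#' heterogeneity distribution, evaluated on the supplied grid.
#'
#' @param state numeric `c(w, s)`.
#' @param p an `izh_params_nd`.
#' @param grid a [beta_grid()].
#' @return Numeric derivative vector of length 2.
#' @export
mfii_rhs <- function(state, p, grid) {
  gp <- grid_params(p, grid)
  R <- firing_rate_izh(state[1], state[2], p, I = gp$I, g = gp$g)
  Rbar <- sum(gp$weight * R)
  wj_R <- sum(gp$weight * gp$w_jump * R)
  abar <- sum(gp$weight * gp$a)
  vb <- if (p$b != 0)
    sum(gp$weight * mean_v_izh(state[1], state[2], p, I = gp$I, g = gp$g))
  else 0
  c(abar * p$b * vb - abar * state[1] + wj_R,
    -state[2] / p$tau_s + p$s_jump * Rbar)
}

#' Right-hand side of the conditioned-adaptation mean field (MFIII)
#'
#' The adaptation field conditioned on the heterogeneous parameters is a
#' transport-free PDE; discretized by the method of lines on the grid nodes
#' it becomes `M + 1` ODEs: one adaptation equation per node plus the shared
#' gating variable, whose source is the grid average of the conditional
#' rates.
#'
#' @param state numeric `c(w_1, ..., w_M, s)`.
#' @param p an `izh_params_nd`.
#' @param grid a [beta_grid()] with `M` rows.
#' @return Numeric derivative vector of length `M + 1`.
#' @export
mfiii_rhs <- function(state, p, grid) {
  gp <- grid_params(p, grid)
  M <- length(gp$weight)
  w <- state[seq_len(M)]
  s <- state[M + 1L]
  R <- firing_rate_izh(w, s, p, I = gp$I, g = gp$g)
  vb <- if (p$b != 0) mean_v_izh(w, s, p, I = gp$I, g = gp$g) else 0
  c(gp$a * (p$b * vb - w) + gp$w_jump * R,
    -s / p$tau_s + p$s_jump * sum(gp$weight * R))
}

#' Grid-averaged mean adaptation of an MFIII state
#'
#' @param state MFIII state vector `c(w_1, ..., w_M, s)` (or a matrix whose
#'   rows are states).
#' @param grid the [beta_grid()] the state lives on.
#' @return The weighted average `<w>` (scalar, or vector for a matrix input).
#' @export
conditional_mean_w <- function(state, grid) {
  w8 <- grid$weight
  if (is.matrix(state)) as.numeric(state[, seq_along(w8), drop = FALSE] %*% w8)
  else sum(state[seq_along(w8)] * w8)
}

mf_state_dim <- function(system, grid) {
  if (system == "mfiii") nrow(grid) + 1L else 2L
}

# deSolve-facing closure for a mean-field system. The parameter resolution
# and (for b = 0, the shipped default) the rate formula are hoisted out of
# the integration loop; equality with the reference RHS functions is
# asserted in the tests.
mf_derivs <- function(system, p, grid) {
  if (p$b != 0)
    return(switch(system,
                  mfi = function(t, y, parms) list(mfi_rhs(y, p)),
                  mfii = function(t, y, parms) list(mfii_rhs(y, p, grid)),
                  mfiii = function(t, y, parms) list(mfiii_rhs(y, p, grid))))
  gp <- grid_params(p, grid)
  alpha <- p$alpha; vp <- p$v_peak; vr <- p$v_reset; er <- p$e_r
  tau_s <- p$tau_s; sj <- p$s_jump
  I <- gp$I; g <- gp$g; w8 <- gp$weight; wj <- gp$w_jump; a <- gp$a
  abar <- sum(w8 * a)
  rate <- function(w, s) {
    cc <- (alpha + g * s) / 2
    H <- I - w - cc * cc + g * er * s
    R <- numeric(length(H))
    pos <- H > 0
    if (any(pos)) {
      sH <- sqrt(H[pos])
      R[pos] <- sH / (atan((vp - cc[pos]) / sH) - atan((vr - cc[pos]) / sH))
    }
    R
  }
  switch(system,
         mfi = function(t, y, parms) {
           R <- rate(y[1], y[2])
           list(c(wj * R - abar * y[1], -y[2] / tau_s + sj * R))
         },
         mfii = function(t, y, parms) {
           R <- rate(y[1], y[2])
           list(c(sum(w8 * wj * R) - abar * y[1],
                  -y[2] / tau_s + sj * sum(w8 * R)))
         },
         mfiii = function(t, y, parms) {
           M <- length(w8)
           R <- rate(y[seq_len(M)], y[M + 1L])
           list(c(wj * R - a * y[seq_len(M)],
                  -y[M + 1L] / tau_s + sj * sum(w8 * R)))
         })
}

#' Integrate a mean-field system
#'
#' Adaptive Runge-Kutta (Dormand-Prince 4/5) integration of MFI, MFII or
#' MFIII. The right-hand sides are continuous but non-smooth where the
#' firing rate switches on (square-root behaviour at `H = 0`); the
#' default tolerances of `1e-8` resolve the switching without event
#' detection.
#'
#' @param system `"mfi"`, `"mfii"` or `"mfiii"`.
#' @param p an `izh_params_nd`.
#' @param grid a [beta_grid()]; required for MFII and MFIII.
#' @param init initial state (defaults to the origin: `w = 0`, `s = 0`).
#' @param t_end end of the integration window (dimensionless time).
#' @param dt_out output sampling interval.
#' @param t_start start time (states before `t_start` are not stored; useful
#'   to skip transients cheaply is not supported - the full window is
#'   integrated - but output can be subset afterwards).
#' @param rtol,atol integrator tolerances.
#' @return An `mf_solution`: data frame with columns `time`, `w_mean`, `s`,
#'   `R_mean`, `v_mean`; for MFIII the node field `<w|beta>` trajectory is
#'   attached as attribute `w_cond` (matrix, one column per node) and the
#'   grid as attribute `grid`.
#' @export
integrate_mf <- function(system = c("mfi", "mfii", "mfiii"), p, grid = NULL,
                         init = NULL, t_end = 2000, dt_out = 0.5,
                         t_start = 0, rtol = 1e-8, atol = 1e-8) {
  system <- match.arg(system)
  stopifnot(inherits(p, "izh_params_nd"))
  if (system != "mfi" && is.null(grid))
    stop(system, " requires a beta_grid", call. = FALSE)
  if (p$tau_s < 1)
    warning("tau_s < 1 (dimensionless): the quasi-steady-state reduction ",
            "assumes the gating variable is no faster than the voltage ",
            "density", call. = FALSE)
  ndim <- mf_state_dim(system, grid)
  if (is.null(init)) init <- numeric(ndim)
  if (length(init) != ndim)
    stop("init has length ", length(init), ", expected ", ndim, call. = FALSE)
  times <- seq(t_start, t_end, by = dt_out)
  out <- deSolve::ode(y = init, times = times,
                      func = mf_derivs(system, p, grid), parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integration failure in ", system, " at t = ",
         max(out[, 1]), call. = FALSE)
  mf_solution(system, p, grid, out)
}

# compiled fixed-step RK4 path (b = 0 only); returns a deSolve-shaped
# matrix (time column first) or NULL on divergence
mf_rk4_run <- function(p, grid, y0, t_end, h = 0.05, dt_out = 0.5,
                       reversed = FALSE, conditioned = FALSE, bound = 1e3) {
  stopifnot(p$b == 0)
  gp <- grid_params(p, grid)
  M <- length(gp$weight)
  thin <- max(1L, round(dt_out / h))
  n_steps <- ceiling(t_end / h)
  res <- mf_rk4_cpp(y0, h, as.integer(n_steps), as.integer(thin),
                    if (reversed) -1L else 1L,
                    rep_len(gp$I, M), rep_len(gp$g, M),
                    rep_len(gp$w_jump, M), rep_len(gp$a, M), gp$weight,
                    p$alpha, p$v_peak, p$v_reset, p$e_r, p$tau_s, p$s_jump,
                    conditioned, bound)
  if (res$diverged) return(NULL)
  res$out
}

# fast attractor integration used by the sweep/cycle machinery; falls back
# to the adaptive reference integrator when the voltage term is on
mf_integrate_fast <- function(system, p, grid, init, t_end, dt_out,
                              h = 0.05) {
  if (p$b == 0) {
    out <- mf_rk4_run(p, grid, init, t_end, h = h, dt_out = dt_out,
                      conditioned = (system == "mfiii"))
    if (is.null(out))
      stop("integration failure in ", system, " (state diverged)",
           call. = FALSE)
    mf_solution(system, p, grid, out)
  } else {
    integrate_mf(system, p, grid, init = init, t_end = t_end,
                 dt_out = dt_out)
  }
}

# assemble derived traces from a deSolve matrix
mf_solution <- function(system, p, grid, out) {
  tt <- out[, 1]
  if (system == "mfiii") {
    M <- nrow(grid)
    wc <- out[, 1 + seq_len(M), drop = FALSE]
    s <- out[, M + 2L]
    gp <- grid_params(p, grid)
    Rm <- vm <- wm <- numeric(length(tt))
    for (i in seq_along(tt)) {
      R <- firing_rate_izh(wc[i, ], s[i], p, I = gp$I, g = gp$g)
      Rm[i] <- sum(gp$weight * R)
      vm[i] <- sum(gp$weight *
                     mean_v_izh(wc[i, ], s[i], p, I = gp$I, g = gp$g))
      wm[i] <- sum(gp$weight * wc[i, ])
    }
    sol <- data.frame(time = tt, w_mean = wm, s = s, R_mean = Rm, v_mean = vm)
    attr(sol, "w_cond") <- wc
  } else {
    w <- out[, 2]; s <- out[, 3]
    if (system == "mfi") {
      Rm <- firing_rate_izh(w, s, p)
      vm <- mean_v_izh(w, s, p)
    } else {
      gp <- grid_params(p, grid)
      Rm <- vm <- numeric(length(tt))
      for (i in seq_along(tt)) {
        R <- firing_rate_izh(w[i], s[i], p, I = gp$I, g = gp$g)
        Rm[i] <- sum(gp$weight * R)
        vm[i] <- sum(gp$weight * mean_v_izh(w[i], s[i], p, I = gp$I,
                                            g = gp$g))
      }
    }
    sol <- data.frame(time = tt, w_mean = w, s = s, R_mean = Rm, v_mean = vm)
  }
  attr(sol, "system") <- system
  attr(sol, "grid") <- grid
  attr(sol, "params") <- p
  class(sol) <- c("mf_solution", "data.frame")
  sol
}

#' @export
print.mf_solution <- function(x, ...) {
  cat(sprintf("%s solution: %d samples over t = [%g, %g]\n",
              toupper(attr(x, "system")), nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  final: w_mean = %.5g, s = %.5g, R_mean = %.5g\n",
              x$w_mean[nrow(x)], x$s[nrow(x)], x$R_mean[nrow(x)]))
  invisible(x)
}

#' Convert a mean-field solution to dimensional traces
#'
#' @param sol an `mf_solution`.
#' @param params the dimensional `izh_params` defining the scales.
#' @return Data frame with `time_ms`, `W_mean_pA`, `g_mean_nS` (using the
#'   grid-mean conductance where `g` is heterogeneous), `R_mean_per_ms`.
#' @export
mf_dimensional_trace <- function(sol, params) {
  stopifnot(inherits(sol, "mf_solution"), inherits(params, "izh_params"))
  sc <- attr(nondimensionalize(params), "scales")
  grid <- attr(sol, "grid")
  g_nd <- if (!is.null(grid) && "g" %in% names(grid))
    sum(grid$g * grid$weight) else params$g_syn / sc$conductance_nS
  data.frame(time_ms = sol$time * sc$time_ms,
             W_mean_pA = sol$w_mean * sc$current_pA,
             g_mean_nS = g_nd * sc$conductance_nS * sol$s,
             R_mean_per_ms = sol$R_mean / sc$time_ms)
}
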