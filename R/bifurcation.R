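#' Autonomous ODE wrapper for bifurcation work
#'
#' The bifurcation tools (equilibrium location, Hopf bisection, criticality
#' probing, unstable-cycle tracking) operate on plain autonomous ODE objects
#' so that analytic test systems can be injected alongside the mean-field
#' reductions.
#'
#' @param rhs function of the state vector returning the derivative.
#' @param n state dimension.
#' @param H_fn optional function of the state returning the
#'   switching-manifold value `H` (used by grazing detection).
#' @param name label.
#' @return An `mf_ode` object.
#' @export
mf_ode <- function(rhs, n, H_fn = NULL, name = "ode") {
  structure(list(rhs = rhs, n = as.integer(n), H_fn = H_fn, name = name),
            class = "mf_ode")
}

#' Parameterized MFI / MFII systems for scans in a dimensional parameter
#'
#' Returns a factory: a function of the scanned dimensional parameter value
#' (`g_syn` in nS or `I_app` in pA) producing the corresponding [mf_ode()].
#' For MFII the heterogeneity must be a single normal parameter and is
#' integrated with a deterministic quadrature so the vector field varies
#' smoothly with the scan parameter (Monte-Carlo noise would break
#' bisection).
#'
#' @param params base `izh_params`.
#' @param scan `"g_syn"` or `"I_app"`.
#' @param het optional single-parameter normal `het_spec` (makes the system
#'   MFII).
#' @param M number of quadrature nodes for MFII.
#' @param grid_mode quadrature for the MFII integral; the default `"dense"`
#'   (density-weighted trapezoid grid) keeps the equilibrium eigenvalues
#'   smooth in the scan parameter - a handful of Gauss-Hermite nodes leaves
#'   visible kinks where single nodes cross firing onset.
#' @return A function `value -> mf_ode`.
#' @export
mf_factory <- function(params, scan = c("g_syn", "I_app"), het = NULL,
                       M = 2001, grid_mode = "dense") {
  scan <- match.arg(scan)
  stopifnot(inherits(params, "izh_params"))
  if (!is.null(het)) {
    stopifnot(inherits(het, "het_spec"), length(het) == 1L)
    if (het[[1]]$kind != "normal")
      stop("MFII bifurcation factories require a normal spec", call. = FALSE)
    if (names(het) == scan)
      stop("cannot scan a heterogeneous parameter's mean this way",
           call. = FALSE)
  }
  function(value) {
    pd <- params
    pd[[scan]] <- value
    pd <- do.call(izh_params, unclass(pd))
    p <- nondimensionalize(pd)
    grid <- if (!is.null(het)) beta_grid(het, pd, M = M, mode = grid_mode)
    name <- sprintf("%s(%s = %g)", if (is.null(het)) "MFI" else "MFII",
                    scan, value)
    ode <- mf_ode(fast_mf_rhs(p, grid), 2L,
                  H_fn = fast_mf_H(p, grid), name = name)
    ode$p <- p
    ode$grid <- grid
    ode
  }
}

# inlined MFI/MFII right-hand side; numerically identical to
# mfi_rhs/mfii_rhs (asserted in the tests) but with the parameter lookups
# and S3 dispatch hoisted out of the integration loop
fast_mf_rhs <- function(p, grid = NULL) {
  gp <- grid_params(p, grid)
  alpha <- p$alpha; vp <- p$v_peak; vr <- p$v_reset; er <- p$e_r
  tau_s <- p$tau_s; sj <- p$s_jump; b <- p$b
  I <- gp$I; g <- gp$g; w8 <- gp$weight; wj <- gp$w_jump
  abar <- sum(w8 * gp$a)
  if (b != 0) {
    # fall back to the reference implementation when the voltage term is on
    if (is.null(grid)) return(function(y) mfi_rhs(y, p))
    return(function(y) mfii_rhs(y, p, grid))
  }
  function(y) {
    cc <- (alpha + g * y[2]) / 2
    H <- I - y[1] - cc * cc + g * er * y[2]
    R <- numeric(length(H))
    pos <- H > 0
    if (any(pos)) {
      sH <- sqrt(H[pos])
      R[pos] <- sH / (atan((vp - cc[pos]) / sH) - atan((vr - cc[pos]) / sH))
    }
    c(sum(w8 * wj * R) - abar * y[1],
      -y[2] / tau_s + sj * sum(w8 * R))
  }
}

fast_mf_H <- function(p, grid = NULL) {
  gp <- grid_params(p, grid)
  alpha <- p$alpha; er <- p$e_r
  I <- gp$I; g <- gp$g
  function(y) {
    cc <- (alpha + g * y[2]) / 2
    max(I - y[1] - cc * cc + g * er * y[2])
  }
}

ode_jacobian <- function(ode, y, h = 1e-7) {
  n <- ode$n
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h * max(1, abs(y[j]))
    J[, j] <- (ode$rhs(y + e) - ode$rhs(y - e)) / (2 * e[j])
  }
  J
}

#' Locate an equilibrium of a two-(or n-)dimensional system
#'
#' Damped Newton iteration on the right-hand side, with the Jacobian by
#' central differences; reports the eigenvalues and a stability flag.
#'
#' @param ode an [mf_ode()].
#' @param guess starting state; for mean-field systems a good guess comes
#'   from [mf_equilibrium_guess()].
#' @param tol residual norm for convergence.
#' @param max_iter Newton iteration cap.
#' @param max_step componentwise Newton step cap (damping).
#' @return An `equilibrium_report`: list with `state`, `residual`,
#'   `jacobian`, `eigenvalues`, `stable`, and `branch` (`"firing"`,
#'   `"quiescent"` or `NA` if the system has no `H_fn`).
#' @export
find_equilibrium <- function(ode, guess, tol = 1e-12, max_iter = 200,
                             max_step = 0.05) {
  stopifnot(inherits(ode, "mf_ode"))
  y <- guess
  for (k in seq_len(max_iter)) {
    f <- ode$rhs(y)
    if (!all(is.finite(f))) stop("root failure: non-finite RHS", call. = FALSE)
    if (sqrt(sum(f^2)) < tol && k > 1) break
    J <- ode_jacobian(ode, y)
    step <- tryCatch(solve(J, -f), error = function(e)
      stop("root failure: singular Jacobian", call. = FALSE))
    y <- y + pmin(pmax(step, -max_step), max_step)
  }
  f <- ode$rhs(y)
  if (sqrt(sum(f^2)) > 1e-8)
    stop("root failure: Newton did not converge from the supplied guess",
         call. = FALSE)
  J <- ode_jacobian(ode, y)
  ev <- eigen(J, only.values = TRUE)$values
  branch <- if (is.null(ode$H_fn)) NA_character_ else
    if (ode$H_fn(y) >= 0) "firing" else "quiescent"
  structure(list(state = y, residual = sqrt(sum(ode$rhs(y)^2)), jacobian = J,
                 eigenvalues = ev, stable = all(Re(ev) < 0), branch = branch),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("equilibrium (%s branch): state = (%s), %s\n",
              x$branch, paste(signif(x$state, 6), collapse = ", "),
              if (x$stable) "stable" else "unstable"))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Steady-state guess for the mean-field equilibrium
#'
#' Uses the firing-branch balance relations `w = (sum w_jump R) / a` and
#' `s = tau_s s_jump R` to reduce the equilibrium problem to a scalar
#' fixed-point equation in the mean rate, solved by bisection.
#'
#' @param p an `izh_params_nd`.
#' @param grid optional [beta_grid()] (MFII).
#' @return State vector `c(w, s)`.
#' @export
mf_equilibrium_guess <- function(p, grid = NULL) {
  gp <- grid_params(p, grid)
  abar <- sum(gp$weight * gp$a)
  f <- function(R) {
    w <- sum(gp$weight * gp$w_jump) / abar * R
    s <- p$tau_s * p$s_jump * R
    Rout <- sum(gp$weight * firing_rate_izh(w, s, p, I = gp$I, g = gp$g))
    R - Rout
  }
  if (f(0) >= 0) return(c(0, 0))
  R <- stats::uniroot(f, c(0, 2), tol = 1e-13)$root
  c(sum(gp$weight * gp$w_jump) / abar * R, p$tau_s * p$s_jump * R)
}

# max real part of the equilibrium eigenvalues along a scan, reusing the
# previous equilibrium as the next guess (simple continuation)
scan_re_lambda <- function(factory, values, guess = NULL) {
  out <- numeric(length(values))
  for (i in seq_along(values)) {
    ode <- factory(values[i])
    eq <- tryCatch(find_equilibrium(ode, default_mf_guess(ode)),
                   error = function(e) {
                     if (is.null(guess)) stop(e)
                     find_equilibrium(ode, guess)
                   })
    guess <- eq$state
    out[i] <- max(Re(eq$eigenvalues))
  }
  out
}

default_mf_guess <- function(ode) {
  if (!is.null(ode$p) && inherits(ode$p, "izh_params_nd"))
    mf_equilibrium_guess(ode$p, ode$grid)
  else rep(0.1, ode$n)
}

#' Bisect for a Hopf bifurcation along a parameter scan
#'
#' Follows the equilibrium across the interval and bisects on the sign of
#' the largest real part of its eigenvalue pair.
#'
#' @param factory a function `value -> mf_ode` (see [mf_factory()]).
#' @param interval length-2 numeric bracket of the scan parameter.
#' @param tol bisection tolerance in scan-parameter units.
#' @param guess optional starting state for the equilibrium at
#'   `interval[1]`.
#' @return A `bifurcation_point` (kind `"hopf"`) with the location, the
#'   eigenvalue pair there, and the equilibrium state; or a
#'   "no-bifurcation" report (kind `"none"`) if the real part does not
#'   change sign over the interval.
#' @export
hopf_bisect <- function(factory, interval, tol = 1e-6, guess = NULL) {
  lo <- interval[1]; hi <- interval[2]
  eq_at <- function(v, g0) {
    ode <- factory(v)
    # the balance-relation guess is usually within Newton reach; fall back
    # to the continuation guess from the previous scan point
    tryCatch(find_equilibrium(ode, default_mf_guess(ode)),
             error = function(e) {
               if (is.null(g0)) stop(e)
               find_equilibrium(ode, g0)
             })
  }
  eq_lo <- eq_at(lo, guess)
  eq_hi <- eq_at(hi, eq_lo$state)
  f_lo <- max(Re(eq_lo$eigenvalues)); f_hi <- max(Re(eq_hi$eigenvalues))
  if (sign(f_lo) == sign(f_hi))
    return(structure(list(kind = "none", interval = interval,
                          re_lambda = c(f_lo, f_hi)),
                     class = "bifurcation_point"))
  g0 <- eq_lo$state
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    eq <- eq_at(mid, g0)
    g0 <- eq$state
    if (sign(max(Re(eq$eigenvalues))) == sign(f_lo)) lo <- mid else hi <- mid
  }
  v <- (lo + hi) / 2
  eq <- eq_at(v, g0)
  structure(list(kind = "hopf", value = v, tol = tol,
                 eigenvalues = eq$eigenvalues, state = eq$state,
                 unstable_side = if (f_lo > 0) "below" else "above"),
            class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  if (x$kind == "none") {
    cat("no bifurcation in interval [", x$interval[1], ",", x$interval[2],
        "]\n")
  } else {
    cat(sprintf("%s bifurcation at %.6g", x$kind, x$value))
    if (!is.null(x$criticality)) cat(" (", x$criticality, "critical )")
    cat("\n")
  }
  invisible(x)
}

# integrate an mf_ode (optionally time-reversed) and return the trajectory;
# `step` switches from adaptive Dormand-Prince to fixed-step RK4, which is
# much faster on vector fields with dense switching kinks (the adaptive
# error control otherwise rejects its way across every kink)
ode_run <- function(ode, y0, t_end, dt_out = 0.5, reversed = FALSE,
                    rtol = 1e-9, atol = 1e-11, bound = 1e3, step = NULL) {
  sgn <- if (reversed) -1 else 1
  derivs <- function(t, y, parms) {
    if (any(!is.finite(y)) || max(abs(y)) > bound)
      stop("diverged", call. = FALSE)
    list(sgn * ode$rhs(y))
  }
  if (!is.null(step) && !is.null(ode$p) && ode$p$b == 0) {
    out <- mf_rk4_run(ode$p, ode$grid, y0, t_end, h = step, dt_out = dt_out,
                      reversed = reversed, conditioned = FALSE,
                      bound = bound)
    if (is.null(out) || out[nrow(out), 1] < t_end - dt_out) return(NULL)
    return(out)
  }
  times <- seq(0, t_end, by = if (is.null(step)) dt_out
               else min(step, dt_out))
  out <- tryCatch(
    if (is.null(step))
      deSolve::ode(y0, times, derivs, NULL, method = "ode45",
                   rtol = rtol, atol = atol)
    else
      deSolve::ode(y0, times, derivs, NULL, method = "rk4"),
    error = function(e) NULL)
  if (is.null(out) || nrow(out) < length(times) ||
      any(!is.finite(out[nrow(out), ])))
    return(NULL)
  if (!is.null(step) && dt_out > step)
    out <- out[seq(1, nrow(out), by = round(dt_out / step)), , drop = FALSE]
  out
}

# oscillation amplitude of a state coordinate over the trajectory tail
tail_amplitude <- function(out, frac = 0.25, col = 3) {
  tl <- out[out[, 1] >= (1 - frac) * max(out[, 1]), col]
  diff(range(tl))
}

#' Track an unstable limit cycle by time-reversed integration
#'
#' Integrates the time-reversed flow from a small perturbation off the
#' (stable) equilibrium; if an unstable cycle surrounds it, the reversed
#' trajectory converges onto that cycle. Returns the sampled cycle and the
#' minimum of the switching function `H` along it.
#'
#' @param ode an [mf_ode()] with 2-dimensional state.
#' @param t_track total reversed integration time.
#' @param pert relative perturbation applied to the equilibrium.
#' @param guess equilibrium guess.
#' @param dt_out trajectory sampling interval.
#' @return List with `converged`, `cycle` (matrix `time, y1, y2` over the
#'   trajectory tail), `min_H`, `amplitude`, and the `equilibrium` report;
#'   `converged = FALSE` flags a diverging reversed flow (no cycle).
#' @export
track_unstable_cycle <- function(ode, t_track = 40000, pert = 0.005,
                                 guess = NULL, dt_out = 0.05,
                                 start_state = NULL) {
  stopifnot(inherits(ode, "mf_ode"), ode$n == 2L)
  if (is.null(guess)) guess <- default_mf_guess(ode)
  eq <- find_equilibrium(ode, guess)
  y0 <- if (is.null(start_state)) eq$state * (1 + pert) + 1e-9
  else start_state
  # coarse phase: converge onto the reversed-time attractor
  out <- ode_run(ode, y0, t_track, dt_out = 2, reversed = TRUE,
                 step = 0.02)
  if (is.null(out))
    return(list(converged = FALSE, cycle = NULL, min_H = NA_real_,
                amplitude = NA_real_, equilibrium = eq))
  # fine phase: sample the cycle densely for envelopes and min H
  fine <- ode_run(ode, out[nrow(out), -1], 2500, dt_out = dt_out,
                  reversed = TRUE, step = 0.02)
  if (is.null(fine))
    return(list(converged = FALSE, cycle = NULL, min_H = NA_real_,
                amplitude = NA_real_, equilibrium = eq))
  minH <- if (is.null(ode$H_fn)) NA_real_ else
    min(apply(fine[, -1, drop = FALSE], 1, ode$H_fn))
  list(converged = TRUE, cycle = fine, min_H = minH,
       amplitude = diff(range(fine[, 3])), equilibrium = eq)
}

#' Classify the criticality of a located Hopf bifurcation
#'
#' Simulation-based probing, suited to slow-fast switching vector fields
#' where normal-form coefficients are out of reach and the stable-cycle
#' amplitude can explode over a tiny parameter window (canard-type
#' growth). The operational discriminator is bistability: at offsets on
#' the stable side of the Hopf point, the flow is started both from a
#' small perturbation of the equilibrium and from a large-amplitude state
#' carried over from the oscillatory side. A subcritical Hopf leaves a
#' large oscillation (or divergence) coexisting with the attracting
#' equilibrium; a supercritical one has a single attractor everywhere, the
#' oscillation amplitude falling continuously to zero. Amplitudes on the
#' unstable side are also measured and their successive ratios reported:
#' where the square-root law is resolvable they approach `sqrt(2)` for
#' doubling offsets.
#'
#' @param factory function `value -> mf_ode`.
#' @param hopf a `bifurcation_point` from [hopf_bisect()], or a numeric
#'   Hopf location (in which case `unstable_side` must be given).
#' @param unstable_side `"above"` or `"below"`; taken from `hopf` when
#'   available.
#' @param offsets relative parameter offsets probed (scaled by
#'   `max(abs(hopf value), 1)`).
#' @param t_max amplitude-equilibration cap per probe.
#' @param amp_tol amplitude below which a trajectory counts as settled on
#'   the equilibrium.
#' @param fixed_step fixed RK4 step for the probe integrations (switching
#'   kinks defeat adaptive step control); `NULL` for adaptive.
#' @return List with `criticality` (`"super"`, `"sub"` or `"unknown"`),
#'   unstable-side `amplitudes`, successive `ratios`, and `hysteresis`
#'   (bistability found on the stable side).
#' @export
classify_criticality <- function(factory, hopf, unstable_side = NULL,
                                 offsets = c(1e-3, 2e-3, 4e-3, 8e-3),
                                 t_max = 60000, amp_tol = 1e-4,
                                 fixed_step = 0.1) {
  mu0 <- if (inherits(hopf, "bifurcation_point")) hopf$value else hopf
  if (is.null(unstable_side))
    unstable_side <- hopf$unstable_side
  side <- if (unstable_side == "above") 1 else -1
  scale <- max(abs(mu0), 1)
  dmu <- offsets * scale

  settle <- function(ode, y0) {
    # integrate in windows until the oscillation amplitude stabilizes or
    # the trajectory has clearly collapsed onto the equilibrium
    amp_prev <- -1
    y <- y0
    t_done <- 0
    repeat {
      out <- ode_run(ode, y, 10000, dt_out = 0.5, step = fixed_step)
      if (is.null(out)) return(list(amp = Inf, y = NULL))
      amp <- tail_amplitude(out)
      y <- out[nrow(out), -1]
      t_done <- t_done + 10000
      if (t_done >= 20000 &&
          ((amp < amp_tol && amp_prev < amp_tol) ||
           (amp_prev > 0 && abs(amp - amp_prev) < 0.02 * max(amp, 1e-12))))
        return(list(amp = amp, y = y))
      if (t_done >= t_max) return(list(amp = amp, y = y))
      amp_prev <- amp
    }
  }
  probe_small <- function(ode) {
    eq <- find_equilibrium(ode, default_mf_guess(ode))
    y0 <- eq$state * (1 + 1e-3) + 1e-9
    settle(ode, y0)
  }

  ## unstable side: oscillation amplitudes from a small perturbation
  amps <- numeric(length(dmu))
  big_state <- NULL
  big_amp <- -Inf
  for (i in seq_along(dmu)) {
    res <- probe_small(factory(mu0 + side * dmu[i]))
    amps[i] <- res$amp
    if (is.finite(res$amp) && res$amp > big_amp && !is.null(res$y)) {
      big_amp <- res$amp
      big_state <- res$y
    }
  }

  ## stable side: bistability between the equilibrium and a carried-over
  ## large-amplitude state, at the two largest offsets
  hysteresis <- NA
  if (!is.null(big_state) && big_amp > 100 * amp_tol) {
    hysteresis <- FALSE
    for (d in rev(dmu)[1:min(2, length(dmu))]) {
      ode <- factory(mu0 - side * d)
      from_big <- settle(ode, big_state)
      big_osc <- !is.finite(from_big$amp) ||
        from_big$amp > max(100 * amp_tol, 0.25 * big_amp)
      if (!big_osc) next
      from_small <- probe_small(ode)
      small_dead <- is.finite(from_small$amp) &&
        from_small$amp < 10 * amp_tol
      if (small_dead) { hysteresis <- TRUE; break }
    }
  }

  finite <- is.finite(amps)
  ratios <- if (sum(finite) >= 2)
    amps[finite][-1] / amps[finite][-sum(finite)] else numeric(0)

  criticality <- if (any(!finite) || isTRUE(hysteresis)) "sub"
  else if (identical(hysteresis, FALSE) && big_amp > 100 * amp_tol) "super"
  else "unknown"
  list(criticality = criticality, amplitudes = amps, ratios = ratios,
       hysteresis = hysteresis, offsets = dmu, side = unstable_side)
}

#' Locate a non-smooth limit-cycle bifurcation by bisection
#'
#' Two kinds are supported. `"grazing"`: the parameter value at which the
#' unstable limit cycle tracked by time-reversed integration becomes
#' tangent to the switching manifold (its minimum of `H` crosses zero).
#' `"lc_saddle_node"`: the smallest parameter value at which a stable
#' limit cycle whose firing rate vanishes over part of its period (a
#' bursting cycle) still exists, located by forward simulation with the
#' attractor state carried from the last value where it persisted.
#'
#' @param factory function `value -> mf_ode`.
#' @param interval length-2 bracket; for `"lc_saddle_node"` the bursting
#'   attractor must exist at `interval[2]` and not at `interval[1]`.
#' @param kind `"grazing"` or `"lc_saddle_node"`.
#' @param tol bisection tolerance in parameter units.
#' @param burst_init initial state used to reach the bursting attractor at
#'   `interval[2]` (default `c(w, s) = (0.25, 0.001)`: large adaptation,
#'   silent network).
#' @param t_settle integration time per probe.
#' @param t_track reversed-tracking time per grazing probe.
#' @return A `bifurcation_point` of the requested kind, or kind `"none"`
#'   when bracketing fails.
#' @export
locate_nonsmooth_bifurcation <- function(factory, interval,
                                         kind = c("grazing",
                                                  "lc_saddle_node"),
                                         tol = 0.02,
                                         burst_init = c(0.25, 0.001),
                                         t_settle = 40000, t_track = 50000) {
  kind <- match.arg(kind)
  lo <- interval[1]; hi <- interval[2]
  if (kind == "grazing") {
    warm <- NULL
    probe <- function(v) {
      tr <- track_unstable_cycle(factory(v), t_track = t_track,
                                 start_state = warm)
      if (!tr$converged) return(NA_real_)
      warm <<- tr$cycle[nrow(tr$cycle), -1]
      tr$min_H
    }
    f_lo <- probe(lo); f_hi <- probe(hi)
    if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi))
      return(structure(list(kind = "none", interval = interval,
                            min_H = c(f_lo, f_hi)),
                       class = "bifurcation_point"))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- probe(mid)
      if (is.na(fm)) return(structure(list(kind = "none", interval = c(lo, hi)),
                                      class = "bifurcation_point"))
      if (sign(fm) == sign(f_lo)) lo <- mid else hi <- mid
    }
    structure(list(kind = "grazing", value = (lo + hi) / 2, tol = tol),
              class = "bifurcation_point")
  } else {
    is_bursting <- function(out, ode) {
      tl <- out[out[, 1] >= 0.8 * max(out[, 1]), , drop = FALSE]
      amp <- diff(range(tl[, 3]))
      if (amp < 1e-3) return(FALSE)
      Hv <- apply(tl[, -1, drop = FALSE], 1, ode$H_fn)
      any(Hv < 0)                      # rate vanishes over part of the cycle
    }
    ode_hi <- factory(hi)
    out <- ode_run(ode_hi, burst_init, t_settle, dt_out = 0.5, step = 0.05)
    if (is.null(out) || !is_bursting(out, ode_hi))
      return(structure(list(kind = "none", interval = interval,
                            note = "no bursting attractor at upper end"),
                       class = "bifurcation_point"))
    state <- out[nrow(out), -1]
    ode_lo <- factory(lo)
    out_lo <- ode_run(ode_lo, state, t_settle, dt_out = 0.5, step = 0.05)
    if (!is.null(out_lo) && is_bursting(out_lo, ode_lo))
      return(structure(list(kind = "none", interval = interval,
                            note = "bursting attractor at lower end too"),
                       class = "bifurcation_point"))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      ode_m <- factory(mid)
      out <- ode_run(ode_m, state, t_settle, dt_out = 0.5, step = 0.05)
      if (!is.null(out) && is_bursting(out, ode_m)) {
        hi <- mid
        state <- out[nrow(out), -1]
      } else lo <- mid
    }
    structure(list(kind = "lc_saddle_node", value = (lo + hi) / 2, tol = tol),
              class = "bifurcation_point")
  }
}

#' Hopf bifurcation curves in the applied-current / conductance plane
#'
#' For each mean applied current, bisects for the low- and high-conductance
#' Hopf points and (optionally) classifies their criticality; the
#' criticality switch along a curve marks a Bautin point.
#'
#' @param params base `izh_params`.
#' @param I_values mean applied currents (pA) to slice at.
#' @param g_interval conductance bracket (nS) containing both Hopf points.
#' @param sigma_I heterogeneity standard deviations (pA); 0 means the
#'   homogeneous MFI system.
#' @param classify if `TRUE`, run [classify_criticality()] at every Hopf
#'   point (slow).
#' @param M Gauss-Hermite nodes for the heterogeneous slices.
#' @return Data frame with columns `sigma_I`, `I_app`, `side`, `g_hopf`,
#'   `criticality`.
#' @export
hopf_curve_2param <- function(params, I_values, g_interval = c(5, 600),
                              sigma_I = 0, classify = FALSE, M = 20) {
  rows <- list()
  for (sig in sigma_I) {
    for (I in I_values) {
      pd <- params; pd$I_app <- I
      pd <- do.call(izh_params, unclass(pd))
      het <- if (sig > 0) het_spec(I_app = dist_normal(I, sig)) else NULL
      fac <- mf_factory(pd, scan = "g_syn", het = het, M = M)
      ## split the interval at the eigenvalue maximum to catch both crossings
      gs <- seq(g_interval[1], g_interval[2], length.out = 13)
      re <- suppressWarnings(tryCatch(scan_re_lambda(fac, gs),
                                      error = function(e) rep(NA, length(gs))))
      if (all(is.na(re)) || all(re < 0, na.rm = TRUE)) next
      ipk <- which.max(re)
      for (side in c("low", "high")) {
        iv <- if (side == "low") c(g_interval[1], gs[ipk])
        else c(gs[ipk], g_interval[2])
        bp <- tryCatch(hopf_bisect(fac, iv, tol = 1e-3),
                       error = function(e) NULL)
        if (is.null(bp) || bp$kind != "hopf") next
        crit <- if (classify)
          classify_criticality(fac, bp)$criticality else NA_character_
        rows[[length(rows) + 1L]] <-
          data.frame(sigma_I = sig, I_app = I, side = side,
                     g_hopf = bp$value, criticality = crit)
      }
    }
  }
  do.call(rbind, rows)
}
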