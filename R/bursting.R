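#' Steady-state attractor of a mean-field system: limit cycle or fixed point
#'
#' Integrates past the transient and detects periodicity with a Poincare
#' section on the gating variable (downward crossings of its trailing
#' mean). If the late-time oscillation amplitude is below `fp_tol` the
#' attractor is reported as a fixed point; otherwise the period is the mean
#' crossing interval, accepted once three successive intervals agree to
#' `period_rtol`, and the cycle is sampled over the final period(s).
#'
#' @param system `"mfi"`, `"mfii"` or `"mfiii"`.
#' @param p an `izh_params_nd`.
#' @param grid a [beta_grid()] for MFII/MFIII.
#' @param init initial state; defaults to a silent, strongly adapted state
#'   (which reaches a bursting attractor when one exists).
#' @param t_transient time discarded before analysis.
#' @param t_sample analysis window length.
#' @param dt_out sampling interval.
#' @param fp_tol amplitude below which the attractor counts as a fixed
#'   point.
#' @param period_rtol relative tolerance for successive crossing intervals.
#' @return A `limit_cycle` object: list with `kind` (`"cycle"` or
#'   `"fixed_point"`), `period`, `trajectory` (the sampled window,
#'   including conditional rates for MFIII), and per-node rate envelopes
#'   `m_beta`, `M_beta` (cycle minima and maxima of `<R|beta_j>`).
#' @export
find_limit_cycle <- function(system = c("mfi", "mfii", "mfiii"), p,
                             grid = NULL, init = NULL, t_transient = 3000,
                             t_sample = 1500, dt_out = 0.25,
                             fp_tol = 1e-5, period_rtol = 0.005) {
  system <- match.arg(system)
  ndim <- mf_state_dim(system, grid)
  if (is.null(init)) {
    init <- numeric(ndim)
    init[seq_len(ndim - 1L)] <- 0.25       # strongly adapted, silent start
    init[ndim] <- 1e-3
  }
  ## transient integrated at coarse output resolution, analysis window fine
  stage1 <- mf_integrate_fast(system, p, grid, init, t_end = t_transient,
                              dt_out = 2)
  final_state <- function(sol) {
    if (system == "mfiii")
      c(attr(sol, "w_cond")[nrow(sol), ], sol$s[nrow(sol)])
    else c(sol$w_mean[nrow(sol)], sol$s[nrow(sol)])
  }
  init2 <- final_state(stage1)
  ## the analysis window is extended (up to three times) when it holds too
  ## few oscillation periods to measure one
  for (attempt in 0:3) {
    sol <- mf_integrate_fast(system, p, grid, init2, t_end = t_sample,
                             dt_out = dt_out)
    s <- sol$s
    amp_try <- diff(range(s))
    if (amp_try < fp_tol) break
    thr_try <- mean(range(s))
    below_try <- s < thr_try
    n_cross <- sum(!below_try[-length(below_try)] & below_try[-1])
    if (n_cross >= 4L) break
    if (attempt == 3L)
      stop("undetermined attractor: fewer than four section crossings in ",
           "the analysis window; increase t_sample", call. = FALSE)
    init2 <- final_state(sol)
    t_sample <- 2 * t_sample
  }
  sol$time <- sol$time + t_transient
  win <- sol
  gp <- grid_params(p, grid)
  amp <- diff(range(win$s))
  if (amp < fp_tol) {
    if (system == "mfiii") {
      wc <- attr(sol, "w_cond")[nrow(sol), ]
      R <- firing_rate_izh(wc, win$s[nrow(win)], p, I = gp$I, g = gp$g)
    } else {
      R <- firing_rate_izh(win$w_mean[nrow(win)], win$s[nrow(win)], p,
                           I = gp$I, g = gp$g)
    }
    return(structure(list(kind = "fixed_point", period = NA_real_,
                          trajectory = win, m_beta = R, M_beta = R,
                          weights = gp$weight, amplitude = amp),
                     class = "limit_cycle"))
  }
  ## Poincare section: downward crossings of the trailing mean of s
  s <- win$s
  thr <- mean(range(s))
  below <- s < thr
  cross <- which(!below[-length(below)] & below[-1])
  tcross <- win$time[cross]
  intervals <- diff(tcross)
  last3 <- utils::tail(intervals, 3)
  if (diff(range(last3)) > period_rtol * mean(last3))
    warning("period estimate varies by more than the tolerance over the ",
            "last three crossings (possible period-doubled or aperiodic ",
            "attractor)", call. = FALSE)
  period <- mean(last3)
  ## envelopes over the final full period
  idx <- win$time >= max(win$time) - period - dt_out
  cyc <- win[idx, ]
  M <- length(gp$weight)
  Rmat <- if (system == "mfiii") {
    wc <- attr(sol, "w_cond")[idx, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(cyc)), function(i)
      firing_rate_izh(wc[i, ], cyc$s[i], p, I = gp$I, g = gp$g)))
  } else {
    do.call(rbind, lapply(seq_len(nrow(cyc)), function(i)
      firing_rate_izh(cyc$w_mean[i], cyc$s[i], p, I = gp$I, g = gp$g)))
  }
  structure(list(kind = "cycle", period = period, trajectory = win,
                 cycle = cyc, m_beta = apply(Rmat, 2, min),
                 M_beta = apply(Rmat, 2, max), weights = gp$weight,
                 amplitude = amp, crossing_intervals = intervals),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  if (x$kind == "fixed_point")
    cat(sprintf("fixed point (oscillation amplitude %.2g)\n", x$amplitude))
  else
    cat(sprintf("limit cycle: period %.4g, s-amplitude %.4g, %d nodes\n",
                x$period, x$amplitude, length(x$m_beta)))
  invisible(x)
}

#' Population fractions of tonic, quiescent and bursting neurons
#'
#' From the per-node firing-rate envelopes over one period of the network
#' oscillation: nodes whose rate stays positive are tonic, nodes whose rate
#' is identically zero are quiescent, and the remainder - rate vanishing
#' over part of the period - are bursting. The Heaviside convention
#' `h(0) = 1` is kept, implemented with a floating-point tolerance.
#'
#' @param lc a [find_limit_cycle()] result (fixed points work too: their
#'   envelopes are constant, so `p_burst = 0`).
#' @param zero_tol rates below this count as zero.
#' @return Named numeric `c(p_tonic, p_q, p_burst)`, summing to 1 exactly.
#' @export
population_fractions <- function(lc, zero_tol = 1e-8) {
  stopifnot(inherits(lc, "limit_cycle"))
  w8 <- lc$weights
  p_tonic <- sum(w8[lc$m_beta > zero_tol])
  p_q <- sum(w8[lc$M_beta <= zero_tol])
  c(p_tonic = p_tonic, p_q = p_q, p_burst = 1 - p_q - p_tonic)
}

#' Values of the strict local maxima of a sampled time series
#'
#' Used to inspect oscillation attractors, for example to detect
#' period-doubled cycles whose successive maxima alternate between two
#' levels.
#'
#' @param x numeric series (assumed regularly sampled).
#' @return Numeric vector of the local-maximum values, in time order.
#' @export
series_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  x[i]
}

#' Bursting-fraction sweep over the current/conductance plane
#'
#' Runs [find_limit_cycle()] + [population_fractions()] for MFIII (or MFI
#' when `sigma_I = 0`) at every point of a rectangular grid of mean applied
#' currents and synaptic conductances.
#'
#' @param I_values mean applied currents (pA).
#' @param g_values synaptic conductances (nS).
#' @param params base `izh_params`.
#' @param sigma_I standard deviation of the applied current (pA); 0 gives
#'   the homogeneous system.
#' @param M grid nodes for MFIII (Gauss-Hermite, deterministic).
#' @param zero_tol passed to [population_fractions()].
#' @param ... further arguments to [find_limit_cycle()].
#' @return Data frame `I_app`, `g_syn`, `p_tonic`, `p_q`, `p_burst`
#'   (`NA` rows record per-point failures).
#' @export
sweep_pburst <- function(I_values, g_values, params, sigma_I = 500, M = 41,
                         zero_tol = 1e-8, ...) {
  stopifnot(inherits(params, "izh_params"))
  rows <- vector("list", length(I_values) * length(g_values))
  n <- 0L
  for (I in I_values) for (g in g_values) {
    n <- n + 1L
    pd <- params; pd$I_app <- I; pd$g_syn <- g
    pd <- do.call(izh_params, unclass(pd))
    p <- nondimensionalize(pd)
    grid <- if (sigma_I > 0)
      beta_grid(het_spec(I_app = dist_normal(I, sigma_I)), pd, M = M,
                mode = "hermite")
    else NULL
    system <- if (sigma_I > 0) "mfiii" else "mfi"
    fr <- tryCatch({
      lc <- find_limit_cycle(system, p, grid, ...)
      population_fractions(lc, zero_tol = zero_tol)
    }, error = function(e) c(p_tonic = NA_real_, p_q = NA_real_,
                             p_burst = NA_real_))
    rows[[n]] <- data.frame(I_app = I, g_syn = g, p_tonic = fr["p_tonic"],
                            p_q = fr["p_q"], p_burst = fr["p_burst"],
                            row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Extract p-burst contours from a sweep
#'
#' Marching-squares contour lines (via [grDevices::contourLines()]) of the
#' bursting fraction on the sweep grid, typically at levels just above 0
#' and just below 1 (the "0%" and "100%" bursting boundaries).
#'
#' @param sweep result of [sweep_pburst()].
#' @param levels contour levels.
#' @return List of data frames (`I_app`, `g_syn`) per contour segment,
#'   named by level.
#' @export
pburst_contours <- function(sweep, levels = c(0.005, 0.995)) {
  I_values <- sort(unique(sweep$I_app))
  g_values <- sort(unique(sweep$g_syn))
  z <- matrix(NA_real_, length(I_values), length(g_values))
  for (r in seq_len(nrow(sweep)))
    z[match(sweep$I_app[r], I_values), match(sweep$g_syn[r], g_values)] <-
      sweep$p_burst[r]
  cl <- grDevices::contourLines(I_values, g_values, z, levels = levels)
  lapply(cl, function(seg)
    structure(data.frame(I_app = seg$x, g_syn = seg$y),
              level = seg$level))
}
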