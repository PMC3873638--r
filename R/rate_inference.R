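#' Steady-state conditional firing-rate map over a parameter grid
#'
#' Tabulates `g(beta) = <R|beta>` at the tonic-firing steady state of the
#' conditioned mean field, either by integrating MFIII to its fixed point
#' (`mode = "dynamics"`) or algebraically at a frozen gating variable
#' (`mode = "fixed_sbar"`): with `s` fixed at `s_bar = tau_s s_jump <R>`,
#' the per-node balance `w = w_jump <R|beta> / a` closes each node's rate
#' equation, which is solved by bracketed root finding (the rate is
#' decreasing in `w`, so the root is unique).
#'
#' @param grid a [beta_grid()] over a single heterogeneous parameter.
#' @param p the base `izh_params_nd`.
#' @param mode `"dynamics"` or `"fixed_sbar"`.
#' @param R_mean unconditioned mean rate (dimensionless) used to fix
#'   `s_bar`; required in `"fixed_sbar"` mode (take it from data or from a
#'   converged MFIII run).
#' @param t_end integration horizon for `"dynamics"` mode.
#' @param tol convergence tolerance on the late-time oscillation of `s`
#'   (dynamics mode errors with "not tonic" if the system still oscillates).
#' @return A `rate_map`: data frame with the dimensionless node values
#'   (`beta`), the dimensional node values (`beta_dim`), and `rate`
#'   (dimensionless), sorted by `beta`; attributes record the parameter
#'   name, `s_bar` and monotonicity.
#' @export
steady_rate_map <- function(grid, p, mode = c("dynamics", "fixed_sbar"),
                            R_mean = NULL, t_end = 4000, tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "izh_params_nd"))
  hp <- attr(grid, "het_params")
  if (length(hp) != 1L)
    stop("steady_rate_map needs a single heterogeneous parameter; use ",
         "multiparam_rate_interpolation for several", call. = FALSE)
  gp <- grid_params(p, grid)
  M <- nrow(grid)
  if (mode == "dynamics") {
    sol <- integrate_mf("mfiii", p, grid, t_end = t_end, dt_out = 1)
    tl <- sol[sol$time >= 0.9 * t_end, ]
    if (diff(range(tl$s)) > max(tol, 1e-4 * max(tl$s)))
      stop("not tonic: MFIII does not converge to a fixed point at these ",
           "parameters", call. = FALSE)
    wc <- attr(sol, "w_cond")[nrow(sol), ]
    s_bar <- sol$s[nrow(sol)]
    rate <- firing_rate_izh(wc, s_bar, p, I = gp$I, g = gp$g)
  } else {
    if (is.null(R_mean))
      stop("fixed_sbar mode needs R_mean", call. = FALSE)
    s_bar <- p$tau_s * p$s_jump * R_mean
    rate <- vapply(seq_len(M), function(j) {
      f <- function(R) R - firing_rate_izh(gp$w_jump[j] / gp$a[j] * R, s_bar,
                                           p, I = gp$I[j], g = gp$g[j])
      if (f(0) >= 0) return(0)
      stats::uniroot(f, c(0, 2), tol = 1e-13)$root
    }, numeric(1))
  }
  nd_field <- het_nd_field(hp)
  beta <- grid[[nd_field]]
  ord <- order(beta)
  out <- data.frame(beta = beta[ord],
                    beta_dim = attr(grid, "dim_nodes")[[hp]][ord],
                    rate = rate[ord])
  structure(out, class = c("rate_map", "data.frame"), param = hp,
            s_bar = s_bar, mode = mode,
            monotone = !is.unsorted(out$rate) || !is.unsorted(-out$rate))
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(paste0("rate map over %s: %d nodes, rates in [%.4g, %.4g] ",
                     "(dimensionless), %smonotone\n"),
              attr(x, "param"), nrow(x), min(x$rate), max(x$rate),
              if (attr(x, "monotone")) "" else "NOT "))
  invisible(x)
}

# derivative of the map by central differences on the (sorted) grid
map_derivative <- function(beta, rate) {
  n <- length(beta)
  d <- numeric(n)
  d[1] <- (rate[2] - rate[1]) / (beta[2] - beta[1])
  d[n] <- (rate[n] - rate[n - 1]) / (beta[n] - beta[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (rate[3:n] - rate[1:(n - 2)]) / (beta[3:n] - beta[1:(n - 2)])
  d
}

check_invertible <- function(map) {
  if (!attr(map, "monotone"))
    stop("rate map is not monotonic; the distribution transform is not ",
         "invertible", call. = FALSE)
  if (any(duplicated(map$rate)))
    stop("rate map is not strictly monotonic (flat segments); restrict the ",
         "grid to the firing region", call. = FALSE)
}

#' Predict the steady-state firing-rate density from a parameter density
#'
#' Pushes the parameter density through the tabulated steady-state rate map
#' by the change-of-variables formula
#' `rho_R(r) = rho_beta(g^{-1}(r)) |d g^{-1} / d r|`, using monotone
#' interpolation of the map and central-difference derivatives.
#'
#' @param map a [steady_rate_map()] over the heterogeneous parameter.
#' @param spec the `dist_spec` of that parameter, in dimensional units.
#' @param rate_unit `"dimensionless"` or `"per_ms"`; `params` is required
#'   for the conversion in the latter case.
#' @param params optional `izh_params` for unit conversion.
#' @return A `density_estimate`: data frame `value`, `density`, normalized
#'   to unit integral over its support, with a `cdf` attribute (function).
#' @export
predict_rate_density <- function(map, spec, rate_unit = c("dimensionless",
                                                          "per_ms"),
                                 params = NULL) {
  rate_unit <- match.arg(rate_unit)
  # quiescent nodes make the map flat at zero; the transform is carried out
  # on the firing region (the predicted density is conditional on firing)
  if (any(map$rate == 0)) {
    map <- map[map$rate > 0, , drop = FALSE]
    attr(map, "monotone") <- !is.unsorted(map$rate) ||
      !is.unsorted(-map$rate)
  }
  check_invertible(map)
  dens_beta <- het_density(spec, map$beta_dim)
  dgdb <- abs(map_derivative(map$beta_dim, map$rate))
  keep <- dgdb > 0
  r <- map$rate[keep]
  dens <- dens_beta[keep] / dgdb[keep]
  if (rate_unit == "per_ms") {
    stopifnot(inherits(params, "izh_params"))
    tc <- time_unit_ms(params)
    r <- r / tc
    dens <- dens * tc
  }
  ord <- order(r)
  density_estimate(r[ord], dens[ord])
}

density_estimate <- function(value, density) {
  density <- pmax(density, 0)
  Z <- pracma::trapz(value, density)
  if (Z <= 0) stop("degenerate density estimate", call. = FALSE)
  density <- density / Z
  cdf_vals <- cumsum(c(0, diff(value) * (utils::head(density, -1) +
                                         utils::tail(density, -1)) / 2))
  cdf_vals <- cdf_vals / cdf_vals[length(cdf_vals)]
  structure(data.frame(value = value, density = density),
            class = c("density_estimate", "data.frame"),
            cdf = stats::approxfun(value, cdf_vals, yleft = 0, yright = 1,
                                   rule = 2))
}

#' Kolmogorov-Smirnov distance between a predicted density and a sample
#'
#' Sup-distance between the predicted cumulative distribution and the
#' empirical one.
#'
#' @param est a `density_estimate`.
#' @param x numeric sample.
#' @return Scalar KS distance.
#' @export
ks_distance <- function(est, x) {
  stopifnot(inherits(est, "density_estimate"))
  cdf <- attr(est, "cdf")
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

#' Count the modes of a density curve
#'
#' Local maxima of the (lightly smoothed) density values that exceed a
#' fraction of the global maximum; used to compare predicted and empirical
#' firing-rate distributions for multimodality.
#'
#' @param est a `density_estimate` (or data frame with `value`, `density`).
#' @param min_rel minimum height of a countable mode, relative to the
#'   highest one.
#' @param smooth width (in grid points) of a moving-average smoother
#'   applied before peak counting.
#' @return Integer mode count.
#' @export
count_modes <- function(est, min_rel = 0.1, smooth = 5) {
  d <- est$density
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    d <- stats::filter(d, k, sides = 2)
    d[is.na(d)] <- est$density[is.na(d)]
    d <- as.numeric(d)
  }
  n <- length(d)
  if (n < 3) return(1L)
  peaks <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  sum(d[peaks] >= min_rel * max(d))
}

#' Empirical rate-density estimate from per-neuron rates
#'
#' Histogram with Freedman-Diaconis bins (the robust default for around a
#' thousand neurons) or a Gaussian kernel estimate.
#'
#' @param rates numeric vector of per-neuron steady-state rates.
#' @param method `"fd"` (histogram) or `"kernel"`.
#' @return A `density_estimate`.
#' @export
estimate_rate_density <- function(rates, method = c("fd", "kernel")) {
  method <- match.arg(method)
  if (method == "fd") {
    h <- graphics::hist(rates, breaks = "FD", plot = FALSE)
    density_estimate(h$mids, h$density)
  } else {
    d <- stats::density(rates)
    density_estimate(d$x, d$y)
  }
}

#' Heterogeneity-smoothed firing-rate curve
#'
#' Averages the single-neuron rate over a distribution of applied currents:
#' `F(I_syn) = integral <R | I + I_syn> rho_I(I) dI` by Gauss-Hermite
#' quadrature. The square-root onset of the homogeneous curve at rheobase
#' is smoothed out for any positive spread.
#'
#' @param spec_I `dist_spec` of the background current, in pA.
#' @param I_syn_pA synaptic-current offsets (pA) at which to evaluate.
#' @param params base `izh_params`.
#' @param M Gauss-Hermite node count (normal specs); mixtures fall back to
#'   dense trapezoid integration.
#' @return Data frame `I_syn_pA`, `rate` (dimensionless rate per unit
#'   dimensionless time).
#' @export
smoothed_fI <- function(spec_I, I_syn_pA, params, M = 40) {
  stopifnot(inherits(spec_I, "dist_spec"), inherits(params, "izh_params"))
  p <- nondimensionalize(params)
  cur <- attr(p, "scales")$current_pA
  if (spec_I$kind == "normal" && spec_I$sd == 0) {
    rate <- firing_rate_izh(0, 0, p, I = (spec_I$mean + I_syn_pA) / cur,
                            g = 0)
    return(data.frame(I_syn_pA = I_syn_pA, rate = rate))
  }
  if (spec_I$kind == "normal") {
    q <- het_quadrature(spec_I, M, mode = "hermite")
    nodes <- q$nodes; w8 <- q$weights
  } else {
    rng <- dist_range(spec_I)
    nodes <- seq(rng[1], rng[2], length.out = 2001)
    w8 <- het_density(spec_I, nodes)
    w8 <- w8 / sum(w8)
  }
  rate <- vapply(I_syn_pA, function(Is)
    sum(w8 * firing_rate_izh(0, 0, p, I = (nodes + Is) / cur, g = 0)),
    numeric(1))
  data.frame(I_syn_pA = I_syn_pA, rate = rate)
}

#' Invert a firing-rate density into a parameter density
#'
#' Given only the steady-state firing-rate distribution of a tonically
#' firing network, reconstructs the density of one heterogeneous parameter.
#' The mean rate fixes the steady gating variable
#' `s_bar = tau_s s_jump <R>`; the conditional rate map at that `s_bar` is
#' built over a parameter grid and the change-of-variables formula
#' `rho_beta(beta) = rho_R(g(beta)) |d g / d beta|` is applied.
#'
#' @param rates per-neuron steady-state rates in dimensionless units, or a
#'   `density_estimate` of them.
#' @param params base `izh_params` (all parameters other than the
#'   heterogeneous one are taken as known).
#' @param param name of the heterogeneous parameter (`"I_app"`, `"g_syn"`
#'   or `"W_jump"`).
#' @param beta_range dimensional range to tabulate the map over.
#' @param n_grid number of map nodes.
#' @return A `density_estimate` over the dimensional parameter values, with
#'   the `rate_map` attached as attribute `map`.
#' @export
invert_rate_density <- function(rates, params, param = "I_app",
                                beta_range, n_grid = 201) {
  stopifnot(inherits(params, "izh_params"))
  p <- nondimensionalize(params)
  if (inherits(rates, "density_estimate")) {
    est <- rates
    R_mean <- pracma::trapz(est$value, est$value * est$density)
  } else {
    est <- estimate_rate_density(rates)
    R_mean <- mean(rates)
  }
  map <- rate_map_over_range(params, param, beta_range, n_grid,
                             R_mean = R_mean)
  check_invertible(map)
  rho_R <- stats::approxfun(est$value, est$density, yleft = 0, yright = 0)
  dgdb <- abs(map_derivative(map$beta_dim, map$rate))
  dens <- rho_R(map$rate) * dgdb
  out <- density_estimate(map$beta_dim, dens)
  attr(out, "map") <- map
  out
}

# uniform-node rate map over a dimensional parameter range at fixed s_bar
rate_map_over_range <- function(params, param, beta_range, n_grid, R_mean) {
  p <- nondimensionalize(params)
  nodes <- seq(beta_range[1], beta_range[2], length.out = n_grid)
  grid <- manual_beta_grid(params, param, nodes)
  steady_rate_map(grid, p, mode = "fixed_sbar", R_mean = R_mean)
}

#' Parameter grid from explicit node values
#'
#' Builds a [beta_grid()] from user-chosen dimensional node values with
#' uniform weights; the usual way to tabulate a rate map over a chosen
#' range for inversion and per-neuron recovery.
#'
#' @param params base `izh_params`.
#' @param param heterogeneous parameter name (`"I_app"`, `"g_syn"`,
#'   `"W_jump"` or `"tau_W"`).
#' @param nodes dimensional node values.
#' @return A `beta_grid`.
#' @export
manual_beta_grid <- function(params, param, nodes) {
  out <- data.frame(row.names = seq_along(nodes))
  out[[het_nd_field(param)]] <- nodes / het_dimless_scale(param, params)
  out$weight <- rep(1 / length(nodes), length(nodes))
  structure(out, class = c("beta_grid", "data.frame"),
            het_params = param, mode = "manual", seed = NULL,
            dim_nodes = stats::setNames(data.frame(nodes), param))
}

#' Recover individual neuron parameters from steady-state rates
#'
#' Monotone inverse interpolation of the steady-state rate map:
#' `beta_hat_i = g^{-1}(R_i)`. Rates outside the image of the map are
#' clamped to its ends (with a warning) unless `clamp = FALSE`.
#'
#' @param rates per-neuron rates, in the same (dimensionless) unit as the
#'   map.
#' @param map a [steady_rate_map()].
#' @param truth optional true dimensional parameter values for scoring.
#' @param clamp clamp out-of-range rates instead of erroring.
#' @return Data frame `rate`, `beta_hat` (dimensional); when `truth` is
#'   given, attribute `mrae` holds the mean relative absolute error.
#' @export
recover_individual_params <- function(rates, map, truth = NULL,
                                      clamp = TRUE) {
  check_invertible(map)
  increasing <- !is.unsorted(map$rate)
  r_lo <- min(map$rate); r_hi <- max(map$rate)
  out_of_range <- rates < r_lo | rates > r_hi
  if (any(out_of_range)) {
    if (!clamp)
      stop(sum(out_of_range), " rates outside the image of the rate map",
           call. = FALSE)
    warning(sum(out_of_range), " rates outside the map image were clamped",
            call. = FALSE)
    rates <- pmin(pmax(rates, r_lo), r_hi)
  }
  inv <- if (increasing)
    stats::splinefun(map$rate, map$beta_dim, method = "hyman")
  else
    stats::splinefun(rev(map$rate), rev(map$beta_dim), method = "hyman")
  beta_hat <- inv(rates)
  res <- data.frame(rate = rates, beta_hat = beta_hat)
  if (!is.null(truth))
    attr(res, "mrae") <- mean(abs(beta_hat - truth) / abs(truth))
  res
}

#' Per-neuron rate prediction under multiple heterogeneous parameters
#'
#' Samples the joint parameter distribution, computes the MFIII
#' steady-state conditional rate at every sample node, and fits a local
#' (distance-weighted) linear interpolant in the standardized parameter
#' space; the sampled rates themselves estimate the rate density.
#'
#' @param het a `het_spec` with two or more heterogeneous parameters.
#' @param params base `izh_params`.
#' @param M Monte-Carlo sample size for the map nodes.
#' @param seed seed for the node draws.
#' @param t_end MFIII integration horizon (steady state required).
#' @param newdata optional data frame of dimensional parameter values at
#'   which to interpolate rates (columns named like the `het` entries).
#' @param k neighbours used by the local linear interpolant.
#' @return List with `nodes` (dimensional sample values + `rate`,
#'   dimensionless), `density` (a `density_estimate` of the sampled rates)
#'   and, when `newdata` is given, `predicted` rates.
#' @export
multiparam_rate_interpolation <- function(het, params, M = 600, seed = 1L,
                                          t_end = 4000, newdata = NULL,
                                          k = 25) {
  stopifnot(inherits(het, "het_spec"), length(het) >= 2L,
            inherits(params, "izh_params"))
  p <- nondimensionalize(params)
  grid <- beta_grid(het, params, M = M, mode = "montecarlo", seed = seed)
  sol <- integrate_mf("mfiii", p, grid, t_end = t_end, dt_out = 1)
  tl <- sol[sol$time >= 0.9 * t_end, ]
  if (diff(range(tl$s)) > 1e-4 * max(max(tl$s), 1e-12))
    stop("not tonic: MFIII oscillates at these parameters", call. = FALSE)
  gp <- grid_params(p, grid)
  wc <- attr(sol, "w_cond")[nrow(sol), ]
  rate <- firing_rate_izh(wc, sol$s[nrow(sol)], p, I = gp$I, g = gp$g)
  nodes <- attr(grid, "dim_nodes")
  nodes$rate <- rate
  res <- list(nodes = nodes,
              density = estimate_rate_density(rate, method = "kernel"))
  if (!is.null(newdata)) {
    nm <- names(het)
    X <- scale(as.matrix(nodes[nm]))
    ctr <- attr(X, "scaled:center"); scl <- attr(X, "scaled:scale")
    Q <- sweep(sweep(as.matrix(newdata[nm]), 2, ctr), 2, scl, "/")
    res$predicted <- vapply(seq_len(nrow(Q)), function(i) {
      d2 <- colSums((t(X) - Q[i, ])^2)
      idx <- order(d2)[seq_len(min(k, nrow(X)))]
      w8 <- 1 / (d2[idx] + 1e-12)
      A <- cbind(1, X[idx, , drop = FALSE] -
                   matrix(Q[i, ], length(idx), ncol(X), byrow = TRUE))
      fit <- stats::lm.wfit(A, rate[idx], w8)
      unname(fit$coefficients[1])
    }, numeric(1))
  }
  res
}
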