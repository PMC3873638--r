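#' Switching-manifold function of the quasi-steady mean field
#'
#' `H = I - w + min_v(F(v) + g (e_r - v) s)`, which for the quadratic
#' `F(v) = v (v - alpha)` evaluates to
#' `I - w - (alpha + g s)^2 / 4 + g e_r s`. The quasi-steady firing rate is
#' positive when `H >= 0` and zero when `H < 0`; the mean-field flow is
#' continuous but not smooth across `H = 0`.
#'
#' All of `w`, `s`, `I` and `g` are recycled to a common length, so the same
#' call serves the homogeneous system and the parameter-resolved ones.
#'
#' @param w mean adaptation (dimensionless).
#' @param s synaptic gating variable (dimensionless).
#' @param p an `izh_params_nd` object.
#' @param I applied current; defaults to `p$I`.
#' @param g synaptic conductance; defaults to `p$g`.
#' @return Numeric vector of `H` values.
#' @export
switching_H <- function(w, s, p, I = p$I, g = p$g) {
  stopifnot(inherits(p, "izh_params_nd"))
  I - w - (p$alpha + g * s)^2 / 4 + g * p$e_r * s
}

#' Quasi-steady firing rate of the Izhikevich mean field (closed form)
#'
#' The reciprocal of the subthreshold passage time from `v_reset` to
#' `v_peak` under frozen `(w, s)`:
#' `sqrt(H) / (atan((v_peak - c)/sqrt(H)) - atan((v_reset - c)/sqrt(H)))`
#' with `c = (alpha + g s)/2`, on the firing branch `H >= 0`; zero on the
#' quiescent branch. Continuous (with value 0) at `H = 0`. Rates are per
#' unit dimensionless time.
#'
#' @inheritParams switching_H
#' @return Numeric vector of firing rates (`>= 0`).
#' @export
firing_rate_izh <- function(w, s, p, I = p$I, g = p$g) {
  stopifnot(inherits(p, "izh_params_nd"))
  n <- max(length(w), length(s), length(I), length(g))
  w <- rep_len(w, n); s <- rep_len(s, n)
  I <- rep_len(I, n); g <- rep_len(g, n)
  cc <- (p$alpha + g * s) / 2
  H <- I - w - cc^2 + g * p$e_r * s
  r <- numeric(n)
  pos <- H > 0
  if (any(pos)) {
    sH <- sqrt(H[pos])
    r[pos] <- sH / (atan((p$v_peak - cc[pos]) / sH) -
                    atan((p$v_reset - cc[pos]) / sH))
  }
  r
}

#' Quasi-steady mean membrane potential of the Izhikevich mean field
#'
#' Time-averaged voltage over one passage on the firing branch,
#' `R/2 * log(((v_peak - c)^2 + H) / ((v_reset - c)^2 + H)) + c`; on the
#' quiescent branch the stable subthreshold equilibrium `c - sqrt(-H)`
#' (the smaller root of `F(v) - w + I + g (e_r - v) s = 0`).
#'
#' @inheritParams switching_H
#' @return Numeric vector of mean voltages (dimensionless).
#' @export
mean_v_izh <- function(w, s, p, I = p$I, g = p$g) {
  stopifnot(inherits(p, "izh_params_nd"))
  n <- max(length(w), length(s), length(I), length(g))
  w <- rep_len(w, n); s <- rep_len(s, n)
  I <- rep_len(I, n); g <- rep_len(g, n)
  cc <- (p$alpha + g * s) / 2
  H <- I - w - cc^2 + g * p$e_r * s
  v <- cc - sqrt(pmax(-H, 0))
  pos <- H >= 0
  if (any(pos)) {
    R <- firing_rate_izh(w[pos], s[pos], p, I[pos], g[pos])
    v[pos] <- R / 2 * log(((p$v_peak - cc[pos])^2 + H[pos]) /
                          ((p$v_reset - cc[pos])^2 + H[pos])) + cc[pos]
  }
  v
}

#' Quasi-steady firing rate by adaptive quadrature (general nonlinearity)
#'
#' Evaluates `[ integral dv / (F(v) - w + I + g (e_r - v) s) ]^{-1}` over
#' `[v_reset, v_peak]` numerically, returning 0 on the quiescent branch.
#' Serves both as the rate formula for a pluggable nonlinearity `F` and as
#' an independent cross-check of [firing_rate_izh()] for the quadratic.
#'
#' @inheritParams switching_H
#' @param Ffun the membrane nonlinearity, a vectorized function of `v`;
#'   defaults to the quadratic `v (v - alpha)`.
#' @param rel.tol relative tolerance passed to [stats::integrate()].
#' @return Scalar firing rate.
#' @export
rate_by_quadrature <- function(w, s, p, I = p$I, g = p$g,
                               Ffun = NULL, rel.tol = 1e-10) {
  stopifnot(inherits(p, "izh_params_nd"),
            length(w) == 1L, length(s) == 1L,
            length(I) == 1L, length(g) == 1L)
  if (is.null(Ffun)) Ffun <- function(v) v * (v - p$alpha)
  denom <- function(v) Ffun(v) - w + I + g * (p$e_r - v) * s
  # quiescent branch: the drift attains a non-positive minimum on the interval
  dmin <- min(stats::optimize(denom, c(p$v_reset, p$v_peak))$objective,
              denom(p$v_reset), denom(p$v_peak))
  if (dmin <= 0) return(0)
  val <- stats::integrate(function(v) 1 / denom(v), p$v_reset, p$v_peak,
                          rel.tol = rel.tol, abs.tol = 0,
                          subdivisions = 500L)$value
  1 / val
}

#' Time-averaged voltage by adaptive quadrature (oracle form)
#'
#' Computes `R * integral v dv / (F(v) - w + I + g (e_r - v) s)` on the
#' firing branch; used to cross-check [mean_v_izh()].
#'
#' @inheritParams rate_by_quadrature
#' @return Scalar mean voltage; `NA` on the quiescent branch.
#' @export
mean_v_by_quadrature <- function(w, s, p, I = p$I, g = p$g, rel.tol = 1e-10) {
  stopifnot(inherits(p, "izh_params_nd"))
  Ffun <- function(v) v * (v - p$alpha)
  denom <- function(v) Ffun(v) - w + I + g * (p$e_r - v) * s
  dmin <- min(stats::optimize(denom, c(p$v_reset, p$v_peak))$objective,
              denom(p$v_reset), denom(p$v_peak))
  if (dmin <= 0) return(NA_real_)
  R <- 1 / stats::integrate(function(v) 1 / denom(v), p$v_reset, p$v_peak,
                            rel.tol = rel.tol, abs.tol = 0,
                            subdivisions = 500L)$value
  R * stats::integrate(function(v) v / denom(v), p$v_reset, p$v_peak,
                       rel.tol = rel.tol, abs.tol = 0,
                       subdivisions = 500L)$value
}
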