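#' Dimensional parameters of an adapting quadratic integrate-and-fire neuron
#'
#' Constructs the full dimensional parameter set of the Izhikevich-type
#' adapting neuron together with the network synapse parameters. Defaults are
#' the CA3 pyramidal-cell fit used throughout the package. The threshold
#' voltage `V_T` defaults to `V_R + 40 - eta_fit/k` with `eta_fit = -1` nS,
#' the value the adaptation conductance was fit at; `eta` itself defaults to
#' 0 so that the shipped configurations drop the voltage-dependent (`b v`)
#' term of the adaptation equation, as is done in all numerical studies here.
#' Set `eta = -1` to restore the fitted value.
#'
#' @param C membrane capacitance (pF).
#' @param k voltage nonlinearity scale (nS/mV).
#' @param V_R resting potential (mV), must be negative.
#' @param V_T threshold potential (mV), with `V_R < V_T < V_peak`.
#' @param V_peak spike cutoff (mV).
#' @param V_reset post-spike reset (mV), below `V_peak`.
#' @param W_jump adaptation increment per spike (pA).
#' @param tau_W adaptation time constant (ms).
#' @param eta voltage-dependent adaptation conductance (nS); 0 disables the
#'   `b v` term.
#' @param I_app applied current (pA).
#' @param g_syn maximal synaptic conductance (nS).
#' @param tau_syn synaptic decay time constant (ms).
#' @param s_jump synaptic gating increment per spike (dimensionless).
#' @param E_r synaptic reversal potential (mV); 0 mV is the excitatory
#'   (AMPA-like) convention used in every shipped configuration.
#'
#' @return An object of class `izh_params` (a named list).
#' @seealso [nondimensionalize()], [rheobase()]
#' @export
#' @examples
#' p <- izh_params(I_app = 2000, g_syn = 200)
#' nondimensionalize(p)
izh_params <- function(C = 250, k = 2.5, V_R = -65, V_T = -24.6,
                       V_peak = 30, V_reset = -55,
                       W_jump = 200, tau_W = 200, eta = 0,
                       I_app = 1500, g_syn = 200, tau_syn = 4,
                       s_jump = 0.8, E_r = 0) {
  p <- list(C = C, k = k, V_R = V_R, V_T = V_T, V_peak = V_peak,
            V_reset = V_reset, W_jump = W_jump, tau_W = tau_W, eta = eta,
            I_app = I_app, g_syn = g_syn, tau_syn = tau_syn,
            s_jump = s_jump, E_r = E_r)
  validate_izh_params(p)
  structure(p, class = "izh_params")
}

validate_izh_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  if (p$C <= 0 || p$k <= 0 || p$tau_W <= 0 || p$tau_syn <= 0)
    stop("invalid parameters: C, k, tau_W and tau_syn must be positive",
         call. = FALSE)
  if (p$s_jump <= 0) stop("invalid parameters: s_jump must be positive",
                          call. = FALSE)
  if (p$V_R >= 0) stop("invalid parameters: V_R must be negative", call. = FALSE)
  if (!(p$V_reset < p$V_peak)) stop("invalid parameters: V_reset < V_peak required",
                                    call. = FALSE)
  if (!(p$V_R < p$V_T && p$V_T < p$V_peak))
    stop("invalid parameters: V_R < V_T < V_peak required", call. = FALSE)
  invisible(p)
}

#' @export
print.izh_params <- function(x, ...) {
  cat("Adapting Izhikevich neuron, dimensional parameters:\n")
  cat(sprintf("  C = %g pF, k = %g nS/mV, V_R = %g mV, V_T = %g mV\n",
              x$C, x$k, x$V_R, x$V_T))
  cat(sprintf("  V_peak = %g mV, V_reset = %g mV, E_r = %g mV\n",
              x$V_peak, x$V_reset, x$E_r))
  cat(sprintf("  W_jump = %g pA, tau_W = %g ms, eta = %g nS\n",
              x$W_jump, x$tau_W, x$eta))
  cat(sprintf("  I_app = %g pA, g_syn = %g nS, tau_syn = %g ms, s_jump = %g\n",
              x$I_app, x$g_syn, x$tau_syn, x$s_jump))
  cat(sprintf("  (dimensionless time unit: %g ms)\n", time_unit_ms(x)))
  invisible(x)
}

#' Millisecond value of one unit of dimensionless time
#'
#' The voltage equation sets the fast time scale `C / (k |V_R|)`; all
#' dimensionless rates and time constants in the package are expressed in
#' this unit.
#'
#' @param p an `izh_params` object.
#' @return Scalar, milliseconds per dimensionless time unit.
#' @export
time_unit_ms <- function(p) {
  stopifnot(inherits(p, "izh_params"))
  p$C / (p$k * abs(p$V_R))
}

#' Nondimensionalize a dimensional parameter set
#'
#' Voltages map through `v = 1 + V/|V_R|` (so `v = 0` at rest), currents and
#' the adaptation variable are scaled by `k V_R^2`, conductances by `k |V_R|`,
#' and time by `C/(k |V_R|)` ms. The returned object carries the scale
#' factors needed to invert the map with [dimensionalize()].
#'
#' @param p an `izh_params` object.
#' @return An object of class `izh_params_nd` with fields `alpha`, `v_peak`,
#'   `v_reset`, `w_jump`, `a`, `b`, `I`, `g`, `tau_s`, `s_jump`, `e_r`.
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "izh_params"))
  vR <- abs(p$V_R)
  cur <- p$k * vR^2            # pA per unit dimensionless current
  con <- p$k * vR              # nS per unit dimensionless conductance
  tms <- p$C / con             # ms per unit dimensionless time
  q <- list(alpha   = 1 + p$V_T / vR,
            v_peak  = 1 + p$V_peak / vR,
            v_reset = 1 + p$V_reset / vR,
            w_jump  = p$W_jump / cur,
            a       = tms / p$tau_W,
            b       = p$eta / con,
            I       = p$I_app / cur,
            g       = p$g_syn / con,
            tau_s   = p$tau_W >= 0, # placeholder, set below
            s_jump  = p$s_jump,
            e_r     = 1 + p$E_r / vR)
  q$tau_s <- p$tau_syn / tms
  structure(q, class = "izh_params_nd",
            scales = list(current_pA = cur, conductance_nS = con,
                          time_ms = tms, voltage_mV = vR, V_R = p$V_R))
}

#' Recover dimensional parameters from a dimensionless set
#'
#' Inverse of [nondimensionalize()]; round-trips to machine precision.
#'
#' @param q an `izh_params_nd` object produced by [nondimensionalize()].
#' @return An `izh_params` object.
#' @export
dimensionalize <- function(q) {
  stopifnot(inherits(q, "izh_params_nd"))
  sc <- attr(q, "scales")
  vR <- sc$voltage_mV
  izh_params(C = sc$time_ms * sc$conductance_nS, k = sc$conductance_nS / vR,
             V_R = sc$V_R, V_T = (q$alpha - 1) * vR,
             V_peak = (q$v_peak - 1) * vR, V_reset = (q$v_reset - 1) * vR,
             W_jump = q$w_jump * sc$current_pA,
             tau_W = sc$time_ms / q$a, eta = q$b * sc$conductance_nS,
             I_app = q$I * sc$current_pA, g_syn = q$g * sc$conductance_nS,
             tau_syn = q$tau_s * sc$time_ms, s_jump = q$s_jump,
             E_r = (q$e_r - 1) * vR)
}

#' @export
print.izh_params_nd <- function(x, ...) {
  cat("Adapting Izhikevich neuron, dimensionless parameters:\n")
  cat(sprintf("  alpha = %.4f, v_peak = %.4f, v_reset = %.4f, e_r = %.4f\n",
              x$alpha, x$v_peak, x$v_reset, x$e_r))
  cat(sprintf("  w_jump = %.4g, a = %.4g, b = %.4g\n", x$w_jump, x$a, x$b))
  cat(sprintf("  I = %.4g, g = %.4g, tau_s = %.4g, s_jump = %.4g\n",
              x$I, x$g, x$tau_s, x$s_jump))
  invisible(x)
}

#' Rheobase of the uncoupled quadratic neuron
#'
#' Minimum current for repetitive firing of the isolated neuron. For the
#' quadratic nonlinearity `F(v) = v (v - alpha)` the dimensionless rheobase
#' is `alpha^2 / 4` (the current cancelling the minimum of `F`); for a
#' dimensional parameter set the value is returned in pA.
#'
#' @param p an `izh_params` or `izh_params_nd` object.
#' @return Scalar rheobase current (pA for dimensional input, dimensionless
#'   otherwise).
#' @export
rheobase <- function(p) UseMethod("rheobase")

#' @export
rheobase.izh_params_nd <- function(p) p$alpha^2 / 4

#' @export
rheobase.izh_params <- function(p) {
  q <- nondimensionalize(p)
  rheobase(q) * attr(q, "scales")$current_pA
}
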