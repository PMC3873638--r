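#' Configuration of a spiking-network simulation
#'
#' Assembles everything a ground-truth network run needs: the neuron count,
#' the base dimensional parameters, an optional heterogeneity specification
#' (per-neuron values are drawn from it with the configuration seed), the
#' simulated duration and the Euler step.
#'
#' @param N number of neurons (`>= 1`).
#' @param params base `izh_params`.
#' @param het optional `het_spec`; parameters it names are drawn per neuron.
#' @param T_sim simulated time (ms).
#' @param dt Euler step (ms); the default 0.025 ms keeps the spike-time
#'   discretization error well below the adaptation time scale.
#' @param seed integer seed controlling both the parameter draws and the
#'   initial voltages.
#' @param trace_dt sampling interval for the recorded mean traces (ms).
#' @return A `network_config` object.
#' @export
network_config <- function(N, params, het = NULL, T_sim = 2000, dt = 0.025,
                           seed = 1L, trace_dt = 1) {
  stopifnot(inherits(params, "izh_params"), N >= 1, dt > 0, T_sim > dt)
  if (!is.null(het)) stopifnot(inherits(het, "het_spec"))
  structure(list(N = as.integer(N), params = params, het = het,
                 T_sim = T_sim, dt = dt, seed = as.integer(seed),
                 trace_dt = trace_dt),
            class = "network_config")
}

#' Simulate the full discontinuous network
#'
#' Forward-Euler integration of the all-to-all coupled network in
#' dimensional form. At every step, neurons whose voltage reached `V_peak`
#' are reset, their adaptation is incremented by their own `W_jump`, and the
#' shared gating variable gains `s_jump / N` per spike (simultaneous spikes
#' all count in the same step). Initial voltages are uniform on
#' `[V_reset, V_peak)` (a desynchronized start), adaptation starts at zero
#' and `s(0) = 0` unless overridden.
#'
#' @param cfg a `network_config`.
#' @param init optional list with elements `V`, `W` (length-`N` vectors) and
#'   `s` overriding the default initial conditions.
#' @return A `network_sim` object: list with `spikes` (data frame
#'   `neuron_id`, `time_ms`), `trace` (data frame `time`, `V_mean`,
#'   `W_mean`, `s`, `g_mean`), `drawn` (per-neuron dimensional parameter
#'   values), the final state, and the configuration.
#' @export
simulate_network <- function(cfg, init = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  p <- cfg$params
  N <- cfg$N

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)

  drawn <- data.frame(I_app = rep(p$I_app, N), g_syn = rep(p$g_syn, N),
                      W_jump = rep(p$W_jump, N), tau_W = rep(p$tau_W, N))
  if (!is.null(cfg$het))
    for (nm in names(cfg$het)) drawn[[nm]] <- het_sample(cfg$het[[nm]], N)
  if (any(drawn$tau_W <= 0))
    stop("heterogeneity drew non-positive tau_W; use truncate_at_zero or a ",
         "tighter spread", call. = FALSE)

  if (is.null(init)) {
    init <- list(V = stats::runif(N, p$V_reset, p$V_peak),
                 W = rep(0, N), s = 0)
  }
  n_steps <- ceiling(cfg$T_sim / cfg$dt)
  trace_every <- max(1L, round(cfg$trace_dt / cfg$dt))

  raw <- simulate_izh_network_cpp(
    drawn$I_app, drawn$g_syn, drawn$W_jump, drawn$tau_W,
    rep(p$eta, N),
    p$C, p$k, p$V_R, p$V_T, p$V_peak, p$V_reset, p$E_r,
    p$tau_syn, p$s_jump, cfg$dt, as.integer(n_steps),
    as.integer(trace_every), init$V, init$W, init$s)

  trace <- raw$trace
  trace$g_mean <- mean(drawn$g_syn) * trace$s
  structure(list(spikes = data.frame(neuron_id = raw$spike_id,
                                     time_ms = raw$spike_t),
                 trace = trace, drawn = drawn,
                 final = list(V = raw$V_final, W = raw$W_final,
                              s = raw$s_final),
                 config = cfg),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("Network simulation: N = %d, T = %g ms, dt = %g ms, %d spikes\n",
              x$config$N, x$config$T_sim, x$config$dt, nrow(x$spikes)))
  invisible(x)
}

spike_times_by_neuron <- function(sim) {
  stopifnot(inherits(sim, "network_sim"))
  split(sim$spikes$time_ms, factor(sim$spikes$neuron_id,
                                   levels = seq_len(sim$config$N)))
}

#' Per-neuron steady-state firing rates from the last interspike interval
#'
#' `R_i = 1 / ISI_{i, last}`; neurons with fewer than two spikes get rate 0.
#'
#' @param sim a `network_sim`.
#' @param unit `"per_ms"` (default) or `"dimensionless"` (per unit of
#'   dimensionless time, using the configuration's time scale).
#' @return Numeric vector of length `N`.
#' @export
steady_rates <- function(sim, unit = c("per_ms", "dimensionless")) {
  unit <- match.arg(unit)
  st <- spike_times_by_neuron(sim)
  r <- vapply(st, function(ts) {
    n <- length(ts)
    if (n < 2L) 0 else 1 / (ts[n] - ts[n - 1L])
  }, numeric(1))
  if (unit == "dimensionless") r <- r * time_unit_ms(sim$config$params)
  unname(r)
}

#' Classify neurons as tonic, bursting or quiescent
#'
#' Within the analysis window, a neuron with no spikes is quiescent; one
#' whose interspike-interval spread satisfies `max(ISI)/min(ISI) >
#' ratio_threshold` is bursting (two ISI scales: within-burst and
#' inter-burst); anything else is tonic. Neurons with a single spike in the
#' window are counted as quiescent.
#'
#' @param sim a `network_sim`.
#' @param window length-2 numeric, analysis window in ms. Default: the final
#'   half of the simulation (transient excluded).
#' @param ratio_threshold ISI max/min ratio separating bursting from tonic.
#' @return A list with `label` (factor of length `N`) and the population
#'   fractions `p_tonic`, `p_burst`, `p_q`.
#' @export
classify_neurons <- function(sim, window = NULL, ratio_threshold = 3) {
  stopifnot(inherits(sim, "network_sim"))
  if (is.null(window))
    window <- c(sim$config$T_sim / 2, sim$config$T_sim)
  if (window[2] <= window[1]) stop("invalid window", call. = FALSE)
  st <- spike_times_by_neuron(sim)
  lab <- vapply(st, function(ts) {
    ts <- ts[ts >= window[1] & ts <= window[2]]
    if (length(ts) < 2L) return("quiescent")
    isi <- diff(ts)
    if (max(isi) / min(isi) > ratio_threshold) "bursting" else "tonic"
  }, character(1))
  lab <- factor(lab, levels = c("tonic", "bursting", "quiescent"))
  tab <- table(lab) / length(lab)
  list(label = lab,
       p_tonic = as.numeric(tab["tonic"]),
       p_burst = as.numeric(tab["bursting"]),
       p_q = as.numeric(tab["quiescent"]))
}
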