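# CA3 parameter table used throughout; b (eta) off as in all shipped runs
table1_params <- function(I_app = 1500, g_syn = 200, ...) {
  izh_params(I_app = I_app, g_syn = g_syn, ...)
}

nd <- function(...) nondimensionalize(table1_params(...))

# small, fast network for unit tests
quick_network <- function(N = 50, I_app = 4500, g_syn = 200, T_sim = 400,
                          het = NULL, seed = 1, dt = 0.05) {
  network_config(N, table1_params(I_app = I_app, g_syn = g_syn), het = het,
                 T_sim = T_sim, dt = dt, seed = seed)
}

# Hopf normal form z' = (mu + i) z + sign * z |z|^2 as an mf_ode factory
normal_form_factory <- function(sign) {
  function(mu) mf_ode(function(y) {
    r2 <- y[1]^2 + y[2]^2
    c(mu * y[1] - y[2] + sign * y[1] * r2,
      y[1] + mu * y[2] + sign * y[2] * r2)
  }, 2L, name = sprintf("normal form (%+d)", sign))
}
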