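test_that("a subthreshold uncoupled neuron never fires repetitively", {
  p <- table1_params(I_app = 800, g_syn = 0)  # below the 1020 pA rheobase
  cfg <- network_config(1, p, T_sim = 1000, dt = 0.025, seed = 1)
  # started at rest: no spike at all
  sim <- simulate_network(cfg, init = list(V = p$V_R, W = 0, s = 0))
  expect_equal(nrow(sim$spikes), 0)
  expect_equal(steady_rates(sim), 0)
  # started above threshold: at most the initial spike, then silence
  sim2 <- simulate_network(cfg)
  expect_lte(nrow(sim2$spikes), 1)
  expect_true(all(sim2$spikes$time_ms < 100))
  expect_equal(steady_rates(sim2), 0)
})

test_that("the gating variable decays exponentially between spikes", {
  cfg <- quick_network(N = 1, I_app = 2000, g_syn = 0, T_sim = 300)
  sim <- simulate_network(cfg)
  tr <- sim$trace
  spikes <- sim$spikes$time_ms
  # longest inter-spike gap, interior samples only
  gaps <- diff(spikes)
  i <- which.max(gaps)
  sel <- tr$time > spikes[i] + 1 & tr$time < spikes[i + 1] - 1
  expect_gt(sum(sel), 5)
  s0 <- tr$s[sel][1]; t0 <- tr$time[sel][1]
  # the Euler scheme decays geometrically with factor (1 - dt/tau) per step
  lam <- log(1 - cfg$dt / cfg$params$tau_syn) / cfg$dt
  pred <- s0 * exp(lam * (tr$time[sel] - t0))
  expect_equal(tr$s[sel], pred, tolerance = 1e-10)
  # which matches the exact exponential to first order in dt
  expect_equal(lam, -1 / cfg$params$tau_syn,
               tolerance = cfg$dt / cfg$params$tau_syn)
})

test_that("steady rates come from the last interspike interval", {
  sim <- list(spikes = data.frame(neuron_id = c(1, 1, 1, 2),
                                  time_ms = c(800, 900, 950, 500)),
              config = list(N = 3, params = table1_params()))
  class(sim) <- "network_sim"
  r <- steady_rates(sim)
  expect_equal(r, c(1 / 50, 0, 0))
  rd <- steady_rates(sim, unit = "dimensionless")
  expect_equal(rd[1], time_unit_ms(table1_params()) / 50)
})

test_that("neuron classification separates the two interspike-interval scales", {
  mk <- function(ts) {
    s <- list(spikes = data.frame(neuron_id = rep(1, length(ts)),
                                  time_ms = ts),
              config = list(N = 1, params = table1_params(), T_sim = 1000))
    class(s) <- "network_sim"
    s
  }
  per <- mk(seq(500, 1000, by = 20))
  expect_equal(as.character(classify_neurons(per)$label), "tonic")
  bur <- mk(500 + cumsum(rep(c(5, 5, 5, 200), 5)))
  cl <- classify_neurons(bur, window = c(500, 1000), ratio_threshold = 3)
  expect_equal(as.character(cl$label), "bursting")
  qui <- mk(numeric(0))
  expect_equal(as.character(classify_neurons(qui)$label), "quiescent")
  expect_error(classify_neurons(per, window = c(900, 100)), "invalid window")
})

test_that("halving the step changes tonic steady statistics by under one percent", {
  # individual spike times shift by O(dt), so pointwise traces of the
  # many-body system decorrelate; the converging quantities are the
  # steady-state statistics
  sim1 <- simulate_network(quick_network(N = 100, T_sim = 800, dt = 0.05))
  sim2 <- simulate_network(quick_network(N = 100, T_sim = 800, dt = 0.025))
  stat <- function(sim) {
    tr <- sim$trace[sim$trace$time > 400, ]
    c(W = mean(tr$W_mean), s = mean(tr$s),
      rate = mean(steady_rates(sim)))
  }
  s1 <- stat(sim1); s2 <- stat(sim2)
  expect_true(all(abs(s1 - s2) / abs(s2) < 0.01))
})

test_that("vanishing heterogeneity collapses neurons onto one trajectory", {
  het <- het_spec(I_app = dist_normal(4500, 1e-6))
  cfg <- quick_network(N = 30, T_sim = 600, het = het)
  sim <- simulate_network(cfg)
  r <- steady_rates(sim)
  expect_lt(diff(range(r)) / mean(r), 0.02)
})

test_that("tonic network rates agree with the mean-field fixed point", {
  cfg <- quick_network(N = 200, I_app = 4500, g_syn = 200, T_sim = 1500,
                       dt = 0.025)
  sim <- simulate_network(cfg)
  r_net <- mean(steady_rates(sim, unit = "dimensionless"))
  p <- nd(I_app = 4500, g_syn = 200)
  eq <- find_equilibrium(mf_factory(table1_params(I_app = 4500,
                                                  g_syn = 200))(200),
                         mf_equilibrium_guess(p))
  r_mf <- firing_rate_izh(eq$state[1], eq$state[2], p)
  expect_lt(abs(r_net - r_mf) / r_mf, 0.02)
})

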