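test_that("subthreshold mean field decays exponentially to the origin", {
  q <- nd(I_app = 500, g_syn = 200)   # below rheobase, H < 0 everywhere
  sol <- integrate_mf("mfi", q, init = c(0.2, 0.3), t_end = 400, dt_out = 1)
  expect_equal(sol$R_mean, rep(0, nrow(sol)))
  expect_equal(sol$w_mean, 0.2 * exp(-q$a * sol$time), tolerance = 1e-6)
  expect_equal(sol$s, 0.3 * exp(-sol$time / q$tau_s), tolerance = 1e-6)
})

test_that("the optimized integrator right-hand sides equal the reference ones", {
  p <- table1_params(I_app = 3000, g_syn = 250)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(3000, 500)), p, M = 15,
                    mode = "hermite")
  d1 <- hetmf:::mf_derivs("mfi", q, NULL)
  d2 <- hetmf:::mf_derivs("mfii", q, grid)
  d3 <- hetmf:::mf_derivs("mfiii", q, grid)
  f2 <- hetmf:::fast_mf_rhs(q, grid)
  set.seed(31)
  for (k in 1:20) {
    y <- c(runif(1, 0, 0.3), runif(1, 0, 0.4))
    expect_equal(d1(0, y, NULL)[[1]], mfi_rhs(y, q), tolerance = 1e-14)
    expect_equal(d2(0, y, NULL)[[1]], mfii_rhs(y, q, grid), tolerance = 1e-14)
    expect_equal(f2(y), mfii_rhs(y, q, grid), tolerance = 1e-14)
    y3 <- c(runif(15, 0, 0.3), runif(1, 0, 0.4))
    expect_equal(d3(0, y3, NULL)[[1]], mfiii_rhs(y3, q, grid),
                 tolerance = 1e-14)
  }
})

test_that("MFII collapses to MFI for degenerate heterogeneity", {
  p <- table1_params(I_app = 3000, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(3000, 1e-9)), p, M = 20,
                    mode = "hermite")
  y <- c(0.1, 0.2)
  expect_equal(mfii_rhs(y, q, grid), mfi_rhs(y, q), tolerance = 1e-10)
  # trajectories too (identical fixed-step integration: phase drift of the
  # bursting cycle under differing adaptive step sequences is not closure
  # error)
  s1 <- hetmf:::mf_integrate_fast("mfi", q, NULL, c(0, 0), 500, 1)
  s2 <- hetmf:::mf_integrate_fast("mfii", q, grid, c(0, 0), 500, 1)
  expect_lt(max(abs(s1$w_mean - s2$w_mean)), 1e-9)
})

test_that("adaptation-increment heterogeneity leaves MFII identical to MFI", {
  # the conditional rate does not depend on w_jump, so the integral
  # collapses to the mean increment and the two reductions coincide
  p <- table1_params(I_app = 3000, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(W_jump = dist_normal(200, 50)), p, M = 20,
                    mode = "hermite")
  s1 <- hetmf:::mf_integrate_fast("mfi", q, NULL, c(0, 0), 1000, 1)
  s2 <- hetmf:::mf_integrate_fast("mfii", q, grid, c(0, 0), 1000, 1)
  expect_lt(max(abs(s1$w_mean - s2$w_mean)), 1e-9)
  expect_lt(max(abs(s1$s - s2$s)), 1e-9)
})

test_that("MFIII with a single node reproduces MFI", {
  p <- table1_params(I_app = 3500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(3500, 1)), p, M = 1,
                    mode = "hermite")
  s1 <- integrate_mf("mfi", q, t_end = 1500, dt_out = 1)
  s3 <- integrate_mf("mfiii", q, grid, t_end = 1500, dt_out = 1)
  expect_lt(max(abs(s1$w_mean - s3$w_mean)), 1e-5)
  expect_lt(max(abs(s1$s - s3$s)), 1e-5)
})

test_that("symmetric MFIII nodes stay symmetric", {
  p <- table1_params(I_app = 3000, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(3000, 1e-12)), p, M = 10,
                    mode = "hermite")
  sol <- integrate_mf("mfiii", q, grid, init = c(rep(0.1, 10), 0.05),
                      t_end = 300, dt_out = 1)
  wc <- attr(sol, "w_cond")
  expect_lt(max(apply(wc, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("grid-averaged adaptation matches direct weighting", {
  grid <- data.frame(I = 1:4, weight = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(conditional_mean_w(c(rep(2, 4), 9), grid), 2)
  expect_equal(conditional_mean_w(c(0, 1, 0, 1, 9),
                                  data.frame(weight = rep(0.25, 4))), 0.5)
})

test_that("tonic fixed points satisfy the steady-state balance relations", {
  q <- nd(I_app = 4500, g_syn = 200)
  sol <- integrate_mf("mfi", q, t_end = 4000, dt_out = 2)
  n <- nrow(sol)
  R <- sol$R_mean[n]
  expect_equal(sol$w_mean[n], q$w_jump / q$a * R, tolerance = 1e-6)
  expect_equal(sol$s[n], q$tau_s * q$s_jump * R, tolerance = 1e-6)
  expect_true(all(sol$R_mean >= 0))
  expect_true(all(sol$s >= -1e-12))
})

test_that("Gauss-Hermite and Monte-Carlo rate integrals agree", {
  p <- table1_params(I_app = 3000, g_syn = 200)
  q <- nondimensionalize(p)
  het <- het_spec(I_app = dist_normal(3000, 500))
  gh <- beta_grid(het, p, M = 20, mode = "hermite")
  mc <- beta_grid(het, p, M = 1e5, mode = "montecarlo", seed = 12)
  y <- c(0.08, 0.15)
  r_gh <- firing_rate_izh(y[1], y[2], q, I = gh$I, g = q$g)
  r_mc <- firing_rate_izh(y[1], y[2], q, I = mc$I, g = q$g)
  se <- stats::sd(r_mc) / sqrt(1e5)
  expect_lt(abs(sum(gh$weight * r_gh) - mean(r_mc)), 3 * se)
})

test_that("integrator convergence: halved tolerances leave the endpoint fixed", {
  q <- nd(I_app = 4500, g_syn = 200)
  s1 <- integrate_mf("mfi", q, t_end = 1000, dt_out = 5, rtol = 1e-8,
                     atol = 1e-8)
  s2 <- integrate_mf("mfi", q, t_end = 1000, dt_out = 5, rtol = 5e-9,
                     atol = 5e-9)
  n <- nrow(s1)
  expect_lt(abs(s1$w_mean[n] - s2$w_mean[n]), 1e-6)
  expect_lt(abs(s1$s[n] - s2$s[n]), 1e-6)
})

test_that("a dimension mismatch or missing grid is caught", {
  q <- nd()
  expect_error(integrate_mf("mfii", q), "requires a beta_grid")
  expect_error(integrate_mf("mfi", q, init = c(1, 2, 3)), "expected 2")
})
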