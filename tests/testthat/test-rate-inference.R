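test_that("a homogeneous rate map is constant at the MFI steady rate", {
  p <- table1_params(I_app = 4500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(4500, 1e-9)), p, M = 5,
                    mode = "hermite")
  map <- steady_rate_map(grid, q, mode = "dynamics", t_end = 3000)
  sol <- integrate_mf("mfi", q, t_end = 3000, dt_out = 5)
  expect_lt(diff(range(map$rate)), 1e-8)
  expect_equal(map$rate[1], sol$R_mean[nrow(sol)], tolerance = 1e-4)
})

test_that("dynamics and fixed-gating map constructions agree at self-consistency", {
  p <- table1_params(I_app = 4500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(4500, 1000)), p, M = 21,
                    mode = "hermite")
  m_dyn <- steady_rate_map(grid, q, mode = "dynamics", t_end = 4000)
  R_mean <- sum(grid$weight * m_dyn$rate[order(order(grid$I))])
  m_fix <- steady_rate_map(grid, q, mode = "fixed_sbar", R_mean = R_mean)
  expect_equal(m_fix$rate, m_dyn$rate, tolerance = 1e-6)
  expect_true(attr(m_dyn, "monotone"))
  # strictly increasing in applied current over the firing region (tail
  # nodes below rheobase are pinned at zero)
  expect_true(all(diff(m_dyn$rate[m_dyn$rate > 0]) > 0))
})

test_that("the oscillatory regime is reported as not tonic", {
  p <- table1_params(I_app = 3500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(3500, 200)), p, M = 11,
                    mode = "hermite")
  expect_error(steady_rate_map(grid, q, mode = "dynamics", t_end = 2000),
               "not tonic")
})

test_that("a locally linear map transforms the density by the Jacobian rule", {
  # synthetic rate map g(beta) = c * beta over the support of the density
  p <- table1_params()
  cc <- 3e-5
  nodes <- seq(1000, 9000, length.out = 301)
  grid <- hetmf:::manual_beta_grid(p, "I_app", nodes)
  map <- structure(data.frame(beta = grid$I, beta_dim = nodes,
                              rate = cc * nodes),
                   class = c("rate_map", "data.frame"), param = "I_app",
                   monotone = TRUE)
  spec <- dist_normal(4500, 800)
  est <- predict_rate_density(map, spec)
  # limited by the trapezoid normalization of the tabulated density
  expect_equal(est$density,
               het_density(spec, est$value / cc) / cc, tolerance = 1e-4)
  expect_equal(pracma::trapz(est$value, est$density), 1, tolerance = 1e-3)
})

test_that("non-monotone maps are rejected as non-invertible", {
  p <- table1_params()
  nodes <- seq(1000, 5000, length.out = 51)
  map <- structure(data.frame(beta = nodes, beta_dim = nodes,
                              rate = sin(nodes / 300)),
                   class = c("rate_map", "data.frame"), param = "I_app",
                   monotone = FALSE)
  expect_error(predict_rate_density(map, dist_normal(3000, 500)),
               "not monotonic")
})

test_that("individual parameters are recovered exactly on noiseless map rates", {
  p <- table1_params(I_app = 4500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- hetmf:::manual_beta_grid(p, "I_app", seq(1500, 8000, by = 25))
  map <- steady_rate_map(grid, q, mode = "fixed_sbar", R_mean = 0.18)
  inv <- stats::splinefun(map$beta_dim, map$rate, method = "hyman")
  truth <- runif(200, 2000, 7500)
  rates <- inv(truth)
  rec <- recover_individual_params(rates, map, truth = truth)
  expect_lt(attr(rec, "mrae"), 1e-5)
  # graceful degradation under 1% multiplicative rate noise
  set.seed(41)
  noisy <- rates * (1 + 0.01 * rnorm(length(rates)))
  rec2 <- suppressWarnings(
    recover_individual_params(pmin(pmax(noisy, min(map$rate)),
                                   max(map$rate)), map, truth = truth))
  expect_lt(attr(rec2, "mrae"), 0.05)
  expect_error(recover_individual_params(max(map$rate) * 2, map,
                                         clamp = FALSE), "outside the image")
})

test_that("forward and inverse density transforms are mutually consistent", {
  p <- table1_params(I_app = 4500, g_syn = 200)
  q <- nondimensionalize(p)
  spec <- dist_normal(4500, 1000)
  grid <- beta_grid(het_spec(I_app = spec), p, M = 41, mode = "hermite")
  map <- steady_rate_map(grid, q, mode = "dynamics", t_end = 4000)
  est_R <- predict_rate_density(map, spec)
  back <- invert_rate_density(est_R, p, param = "I_app",
                              beta_range = c(1200, 9000), n_grid = 301)
  mu_hat <- pracma::trapz(back$value, back$value * back$density)
  sd_hat <- sqrt(pracma::trapz(back$value,
                               (back$value - mu_hat)^2 * back$density))
  expect_lt(abs(mu_hat - 4500) / 4500, 0.02)
  expect_lt(abs(sd_hat - 1000) / 1000, 0.10)
})

test_that("the smoothed rate-current curve loses the square-root onset", {
  p <- table1_params()
  I_rh <- rheobase(p)
  # zero spread: identical to the homogeneous curve, zero below rheobase
  f0 <- smoothed_fI(dist_normal(0, 0), c(-200, 0, 200) + I_rh, p)
  q <- nondimensionalize(p)
  expect_equal(f0$rate[2], 0, tolerance = 1e-10)
  expect_equal(f0$rate[3],
               firing_rate_izh(0, 0, q, I = (I_rh + 200) / (2.5 * 65^2),
                               g = 0), tolerance = 1e-10)
  # positive spread: strictly positive rate slightly below rheobase
  fs <- smoothed_fI(dist_normal(0, 300), I_rh - 100, p)
  expect_gt(fs$rate, 1e-4)
  # Gauss-Hermite agrees with brute-force summation over +-6 sd; spectral
  # accuracy holds when the rate onset kink lies outside the support
  brute_at <- function(offset) {
    Ig <- seq(-600, 600, by = 0.5)
    w8 <- dnorm(Ig, 0, 100); w8 <- w8 / sum(w8)
    sum(w8 * firing_rate_izh(0, 0, q, I = (Ig + I_rh + offset) / (2.5 * 65^2),
                             g = 0))
  }
  gh_smooth <- smoothed_fI(dist_normal(0, 100), I_rh + 700, p, M = 60)
  expect_equal(gh_smooth$rate, brute_at(700), tolerance = 1e-7)
  # with the kink inside the support the quadratures still agree closely
  gh_kink <- smoothed_fI(dist_normal(0, 100), I_rh + 50, p, M = 60)
  expect_equal(gh_kink$rate, brute_at(50), tolerance = 5e-3)
})

test_that("mode counting identifies unimodal and bimodal densities", {
  x <- seq(0, 10, length.out = 500)
  uni <- density_est <- hetmf:::density_estimate(x, dnorm(x, 5, 1))
  bi <- hetmf:::density_estimate(x, 0.5 * dnorm(x, 3, 0.5) +
                                   0.5 * dnorm(x, 7, 0.5))
  expect_equal(count_modes(uni), 1L)
  expect_equal(count_modes(bi), 2L)
})

test_that("multi-parameter interpolation agrees with the single-parameter map", {
  p <- table1_params(I_app = 4500, g_syn = 200)
  q <- nondimensionalize(p)
  het2 <- het_spec(I_app = dist_normal(4500, 800),
                   g_syn = dist_normal(200, 10))
  res <- multiparam_rate_interpolation(het2, p, M = 400, seed = 13,
                                       t_end = 3000,
                                       newdata = data.frame(I_app = 4600,
                                                            g_syn = 200))
  # held-out check: direct MFIII rate at the query point
  grid1 <- beta_grid(het_spec(I_app = dist_normal(4500, 800)), p, M = 41,
                     mode = "hermite")
  map1 <- steady_rate_map(grid1, q, mode = "dynamics", t_end = 3000)
  direct <- stats::approx(map1$beta_dim, map1$rate, xout = 4600)$y
  expect_lt(abs(res$predicted - direct) / direct, 0.02)
  expect_s3_class(res$density, "density_estimate")
})
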