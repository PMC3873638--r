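test_that("population fractions follow the envelope sign structure", {
  mk_lc <- function(m, M, w8) structure(
    list(kind = "cycle", m_beta = m, M_beta = M, weights = w8),
    class = "limit_cycle")
  # all nodes keep firing through the cycle
  lc <- mk_lc(rep(0.1, 4), rep(0.2, 4), rep(0.25, 4))
  expect_equal(population_fractions(lc),
               c(p_tonic = 1, p_q = 0, p_burst = 0))
  # half firing, half silent
  lc2 <- mk_lc(c(0.1, 0.1, 0, 0), c(0.2, 0.2, 0, 0), rep(0.25, 4))
  expect_equal(population_fractions(lc2),
               c(p_tonic = 0.5, p_q = 0.5, p_burst = 0))
  # fractions always sum to one and lie in [0, 1]
  set.seed(51)
  for (k in 1:20) {
    m <- runif(10, -0.1, 0.2); M <- pmax(m, 0) + runif(10, 0, 0.1)
    w8 <- runif(10); w8 <- w8 / sum(w8)
    fr <- population_fractions(mk_lc(pmax(m, 0), M, w8))
    expect_equal(sum(fr), 1)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("weighted fractions match a dense indicator integral", {
  # synthetic piecewise envelopes over a normal parameter: firing for
  # beta > b1, silent for beta < b0, bursting between
  b0 <- -0.3; b1 <- 0.8
  spec <- dist_normal(0, 1)
  q <- het_quadrature(spec, 4001, mode = "dense")
  m <- ifelse(q$nodes > b1, 0.1, 0)
  M <- ifelse(q$nodes > b0, 0.2, 0)
  lc <- structure(list(kind = "cycle", m_beta = m, M_beta = M,
                       weights = q$weights), class = "limit_cycle")
  fr <- population_fractions(lc)
  # agreement is limited by one boundary cell's probability mass
  expect_equal(fr[["p_tonic"]], pnorm(b1, lower.tail = FALSE),
               tolerance = 5e-3)
  expect_equal(fr[["p_q"]], pnorm(b0), tolerance = 5e-3)
})

test_that("zero-tolerance variations do not move fractions materially", {
  p <- table1_params(I_app = 2500, g_syn = 200)
  q <- nondimensionalize(p)
  grid <- beta_grid(het_spec(I_app = dist_normal(2500, 500)), p, M = 41,
                    mode = "hermite")
  lc <- find_limit_cycle("mfiii", q, grid, t_transient = 2000,
                         t_sample = 1200)
  fr1 <- population_fractions(lc, zero_tol = 1e-10)
  fr2 <- population_fractions(lc, zero_tol = 1e-6)
  expect_lt(max(abs(fr1 - fr2)), max(grid$weight) + 1e-12)
})

test_that("tonic and bursting attractors are told apart", {
  q_t <- nd(I_app = 4500, g_syn = 200)
  lc_t <- find_limit_cycle("mfi", q_t, t_transient = 2000, t_sample = 800)
  expect_equal(lc_t$kind, "fixed_point")
  expect_equal(population_fractions(lc_t)[["p_burst"]], 0)

  q_b <- nd(I_app = 3500, g_syn = 200)
  lc_b <- find_limit_cycle("mfi", q_b, t_transient = 2000, t_sample = 1200)
  expect_equal(lc_b$kind, "cycle")
  expect_equal(min(lc_b$m_beta), 0)      # rate vanishes during the cycle
  expect_equal(population_fractions(lc_b)[["p_burst"]], 1)
  # periodicity self-check: successive crossing intervals agree
  iv <- utils::tail(lc_b$crossing_intervals, 2)
  expect_lt(abs(diff(iv)) / mean(iv), 0.005)
})

test_that("local maxima extraction finds alternating peaks", {
  t <- seq(0, 40 * pi, by = 0.05)
  x <- sin(t) * rep_len(c(1, 1), length(t)) +
    0.3 * sin(t / 2)                      # period-two modulation
  mx <- series_local_maxima(x)
  expect_gt(length(mx), 10)
  d <- abs(diff(mx)) / mean(abs(mx))
  expect_gt(mean(d), 0.05)               # alternation visible
  expect_identical(series_local_maxima(c(1, 2)), numeric(0))
})

test_that("contours are extracted from a sweep field", {
  sw <- expand.grid(I_app = 1:5 * 1000, g_syn = 1:5 * 100)
  sw$p_burst <- with(sw, as.numeric(I_app <= 3000 & g_syn <= 300))
  sw$p_tonic <- 1 - sw$p_burst
  sw$p_q <- 0
  cl <- pburst_contours(sw, levels = 0.5)
  expect_gt(length(cl), 0)
  expect_named(cl[[1]], c("I_app", "g_syn"))
})
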