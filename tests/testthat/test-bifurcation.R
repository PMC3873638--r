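test_that("equilibria satisfy the steady-state balance relations", {
  fac <- mf_factory(table1_params(I_app = 4500, g_syn = 200))
  ode <- fac(200)
  eq <- find_equilibrium(ode, mf_equilibrium_guess(ode$p))
  expect_lt(eq$residual, 1e-10)
  expect_true(eq$stable)               # tonic firing: stable focus
  expect_equal(eq$branch, "firing")
  q <- ode$p
  R <- firing_rate_izh(eq$state[1], eq$state[2], q)
  expect_equal(eq$state[1], q$w_jump / q$a * R, tolerance = 1e-8)
  expect_equal(eq$state[2], q$tau_s * q$s_jump * R, tolerance = 1e-8)
})

test_that("the quiescent branch has the origin as equilibrium", {
  fac <- mf_factory(table1_params(I_app = 500, g_syn = 100))
  eq <- find_equilibrium(fac(100), c(0.01, 0.01))
  expect_equal(eq$state, c(0, 0), tolerance = 1e-9)
  expect_equal(eq$branch, "quiescent")
  expect_true(eq$stable)
})

test_that("Hopf bisection locates an analytic Hopf point exactly", {
  # linear focus with Re(lambda) = mu - 0.3: Hopf at mu = 0.3
  fac <- function(mu) mf_ode(function(y)
    c((mu - 0.3) * y[1] - y[2], y[1] + (mu - 0.3) * y[2]), 2L)
  bp <- hopf_bisect(fac, c(-1, 1), tol = 1e-8, guess = c(0, 0))
  expect_equal(bp$kind, "hopf")
  expect_equal(bp$value, 0.3, tolerance = 1e-7)
  expect_equal(bp$unstable_side, "above")
  # no crossing in a one-sided interval
  none <- hopf_bisect(fac, c(-1, 0), tol = 1e-6, guess = c(0, 0))
  expect_equal(none$kind, "none")
})

test_that("bisection of the mean-field Hopf is Cauchy under tolerance halving", {
  fac <- mf_factory(table1_params(I_app = 2000, g_syn = 200))
  b1 <- hopf_bisect(fac, c(5, 150), tol = 1e-3)
  b2 <- hopf_bisect(fac, c(5, 150), tol = 5e-4)
  expect_lt(abs(b1$value - b2$value), 1e-3)
  expect_lt(abs(Re(b1$eigenvalues[1])), 1e-6)
  expect_gt(abs(Im(b1$eigenvalues[1])), 0.01)
})

test_that("time reversal converts a stable normal-form cycle into an attractor", {
  # supercritical normal form at mu = 0.04: stable cycle radius 0.2
  fac <- normal_form_factory(-1)
  ode <- fac(0.04)
  tr <- track_unstable_cycle(mf_ode(function(y) -ode$rhs(y), 2L),
                             t_track = 2000, guess = NULL)
  # reversing the reversed system recovers the forward flow; track the
  # cycle of the double-reversed (i.e. forward-stable) system
  expect_true(tr$converged)
  r <- sqrt(rowSums(tr$cycle[, -1]^2))
  expect_equal(mean(r), 0.2, tolerance = 0.01)
})

test_that("the tracked mean-field cycle is genuinely unstable forward in time", {
  fac <- mf_factory(table1_params(I_app = 2000, g_syn = 200))
  ode <- fac(54)
  tr <- track_unstable_cycle(ode, t_track = 30000)
  expect_true(tr$converged)
  expect_gt(tr$min_H, 0)               # smooth cycle between Hopf and grazing
  # forward integration from the cycle departs from it
  y0 <- tr$cycle[nrow(tr$cycle), -1]
  fwd <- hetmf:::ode_run(ode, y0, 4000, dt_out = 1)
  amp_end <- diff(range(fwd[fwd[, 1] > 3000, 3]))
  # departs the cycle: collapses inward to the focus or blows outward to
  # the bursting attractor
  expect_true(amp_end < 0.5 * tr$amplitude || amp_end > 1.5 * tr$amplitude)
})

test_that("criticality classifier is exact on both normal forms", {
  for (decade in c(1, 10)) {
    cs <- classify_criticality(normal_form_factory(-1), 0,
                               unstable_side = "above",
                               offsets = decade * c(1e-3, 2e-3, 4e-3, 8e-3))
    expect_equal(cs$criticality, "super")
    expect_false(cs$hysteresis)
    # square-root amplitude law: doubling the offset scales by sqrt(2)
    expect_equal(cs$ratios, rep(sqrt(2), 3), tolerance = 0.05)
    cb <- classify_criticality(normal_form_factory(1), 0,
                               unstable_side = "above",
                               offsets = decade * c(1e-3, 2e-3, 4e-3, 8e-3))
    expect_equal(cb$criticality, "sub")
  }
})

test_that("grazing and cycle collision bracket failures are reported", {
  fac <- mf_factory(table1_params(I_app = 2000, g_syn = 200))
  # no sign change: both ends on the smooth side of the unstable cycle
  res <- locate_nonsmooth_bifurcation(fac, c(55.5, 56.5), kind = "grazing",
                                      tol = 0.5)
  expect_equal(res$kind, "none")
  # no bursting attractor anywhere near the upper end
  res2 <- locate_nonsmooth_bifurcation(fac, c(20, 30),
                                       kind = "lc_saddle_node", tol = 0.5,
                                       t_settle = 5000)
  expect_equal(res2$kind, "none")
})

test_that("the two-parameter scan finds both Hopf points per current slice", {
  curves <- hopf_curve_2param(table1_params(), I_values = c(2000, 2500),
                              g_interval = c(5, 600), sigma_I = 0)
  expect_equal(nrow(curves), 4)
  for (I in c(2000, 2500)) {
    slice <- curves[curves$I_app == I, ]
    expect_setequal(slice$side, c("low", "high"))
    expect_lt(slice$g_hopf[slice$side == "low"],
              slice$g_hopf[slice$side == "high"])
  }
  # the boundary moves continuously with the drive: no jumps beyond the
  # spacing of the slices
  low <- curves$g_hopf[curves$side == "low"]
  expect_lt(abs(diff(low)), 30)
})
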