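test_that("threshold delay reduces to (x2 - x1)/g for constant maturation", {
  cfg <- cfg_fixed()                          # g = 0.4
  expect_equal(threshold_delay(0.6, cfg), 2.5, tolerance = 1e-12)
  tr <- maturity_trajectory(0.6, cfg)
  # linear trajectory from x2 down to x1
  ss <- seq(0, tr$tau, length.out = 7)
  expect_equal(tr$y(ss), 1 - 0.4 * ss, tolerance = 1e-10)
  expect_equal(tr$y(0), cfg$mat$x2)
  expect_equal(tr$y(tr$tau), cfg$mat$x1, tolerance = 1e-10)
})

test_that("threshold identity holds along computed trajectories", {
  # integral of g along the trajectory equals the maturity interval length
  cfgs <- list(scenario("(s)_d,(pv)_1", g0 = 0.5, p = 2),
               scenario("(s)_s,(pv)_2,(px)_1,quadratic", g0 = 0.2, p = 2))
  psi <- function(theta) 0.5 + 0.2 * sin(theta)
  for (cfg in cfgs) {
    tr <- maturity_trajectory(psi, cfg, h = cfg$h)
    expect_gt(tr$tau, 0); expect_lt(tr$tau, cfg$h)
    gl <- pracma::gaussLegendre(64, 0, tr$tau)
    lhs <- sum(gl$w * g_rate(tr$y(gl$x), psi(-gl$x), cfg$mat))
    expect_equal(lhs, cfg$mat$x2 - cfg$mat$x1, tolerance = 1e-7)
    # trajectory is strictly decreasing with the correct endpoints
    ys <- tr$y(seq(0, tr$tau, length.out = 50))
    expect_true(all(diff(ys) < 0))
    expect_equal(ys[1], cfg$mat$x2, tolerance = 1e-9)
    expect_equal(ys[50], cfg$mat$x1, tolerance = 1e-7)
  }
})

test_that("event-detected delay matches the integral threshold condition", {
  # same maturity-independent g presented once as polynomial profiles
  # (integral route) and once as opaque functions (generic event route)
  psi <- function(theta) 0.6 + 0.25 * cos(2 * theta)
  cfg_poly <- scenario("(s)_d,(pv)_1", g0 = 0.5, p = 2)
  mt_fun <- maturation_params(g0 = 0.5, k1 = 1, k2 = 0,
                              a_u = function(x) rep(0.9, length(x)),
                              p_u = function(x) rep(2, length(x)))
  cfg_fun <- model_config(cfg_poly$stem, mt_fun, h = cfg_poly$h)
  t1 <- maturity_trajectory(psi, cfg_poly, h = 30)
  t2 <- maturity_trajectory(psi, cfg_fun, h = 30)
  expect_equal(t1$solver, "integral-condition")
  expect_equal(t2$solver, "ode-event")
  expect_equal(t1$tau, t2$tau, tolerance = 1e-9)
})

test_that("histories that never cross the inner maturity bound are rejected", {
  cfg <- cfg_fixed()
  expect_error(threshold_delay(0.6, cfg, h = 2), "horizon")
  expect_error(maturity_trajectory(function(th) rep(0.6, length(th)),
                                   cfg, h = 1), "horizon")
  expect_error(history_pair(1, function(th) th, h = 2), "nonnegative")
})

test_that("the right-hand-side functional vanishes exactly at equilibria", {
  cfg <- cfg_fixed()
  eq <- positive_equilibrium(cfg)
  expect_equal(rhs_F(history_pair(eq$w, eq$v, cfg$h), cfg), c(0, 0),
               tolerance = 1e-11)
  expect_equal(rhs_F(history_pair(0, 0, cfg$h), cfg), c(0, 0))
  # non-equilibrium constants give the closed-form unbalanced rates
  Fc <- rhs_F(history_pair(2, 0.3, cfg$h), cfg)
  expect_equal(Fc[1], q_rate(0.3, cfg$stem) * 2)
  expect_equal(Fc[2], gamma_rate(0.3, cfg$stem) * 2 - cfg$stem$mu * 0.3)
})

test_that("solution-manifold residual separates compatible states", {
  cfg <- cfg_fixed()
  eq <- positive_equilibrium(cfg)
  expect_lt(solution_manifold_residual(history_pair(eq$w, eq$v, cfg$h), cfg),
            1e-10)
  expect_gt(solution_manifold_residual(history_pair(2, 0.3, cfg$h), cfg),
            1e-3)
})

test_that("equilibrium histories are fixed points of the integrator", {
  cfg <- cfg_eta15(p = 5, mu = 2)
  eq <- positive_equilibrium(cfg)
  h <- 2 * eq$tau_eq
  sol <- integrate_sdde(history_pair(eq$w, eq$v, h), cfg, t_end = 50)
  expect_lt(max(abs(sol$path$w - eq$w), abs(sol$path$v - eq$v)), 1e-8)
  # zero initial data stays identically zero
  sol0 <- integrate_sdde(history_pair(0, 0, h), cfg, t_end = 5)
  expect_equal(max(abs(sol0$path$w), abs(sol0$path$v)), 0)
})

test_that("perturbations of a stable equilibrium decay and smooth out", {
  # (mu, p) = (2, 5) lies inside the analytic stability region for eta = 1.5
  cfg <- cfg_eta15(p = 5, mu = 2)
  eq <- positive_equilibrium(cfg)
  expect_gt(analytic_crossing_p(2, cfg)$p, 5)   # indeed below the boundary
  h <- 2 * eq$tau_eq
  sol <- integrate_sdde(history_pair(1.1 * eq$w, 1.1 * eq$v, h), cfg,
                        t_end = 30, dt = 0.03)
  dev_end <- abs(sol$path$v[nrow(sol$path)] - eq$v)
  expect_lt(dev_end, 0.05 * abs(0.1 * eq$v))
  # after the initial transient the segments lie on the solution manifold
  res <- solution_residual(sol, t_sample = c(2 * h, 20))
  expect_lt(max(res$residual), 1e-6)
})
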