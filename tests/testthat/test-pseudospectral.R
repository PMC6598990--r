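test_that("collocation nodes are Chebyshev extrema spanning [-h, 0]", {
  expect_equal(cheb_nodes(1, 2), c(0, -2))
  expect_equal(cheb_nodes(2, 2), c(0, -1, -2))
  for (M in c(1, 4, 9, 16)) {
    nd <- cheb_nodes(M, 3.7)
    expect_equal(nd[1], 0)
    expect_equal(nd[M + 1], -3.7)
    expect_true(all(diff(nd) < 0))
  }
  expect_error(cheb_nodes(0, 1), "at least 1")
})

test_that("the differentiation matrix is exact on the polynomial space", {
  d1 <- cheb_disc(1, 2)
  expect_equal(d1$D, matrix(c(0.5, 0.5, -0.5, -0.5), 2, 2), tolerance = 1e-14)
  disc <- cheb_disc(12, 1.7)
  expect_lt(max(abs(rowSums(disc$D))), 1e-12)        # constants
  expect_equal(as.vector(disc$D %*% disc$nodes), rep(1, 13),
               tolerance = 1e-12)                    # linear
  for (k in 2:12) {                                  # all monomials up to M
    expect_equal(as.vector(disc$D %*% disc$nodes^k),
                 k * disc$nodes^(k - 1), tolerance = 1e-9)
  }
})

test_that("barycentric interpolation is exact at nodes and spectrally accurate", {
  disc <- cheb_disc(9, 2)
  vals <- sin(disc$nodes)
  expect_equal(interp_eval(vals, disc, disc$nodes), vals)   # delta property
  # degree-M polynomial data reproduced exactly off the nodes
  pol <- function(x) 1 - 2 * x + 0.3 * x^5 - x^9
  set.seed(9)
  th <- runif(50, -2, 0)
  expect_equal(interp_eval(pol(disc$nodes), disc, th), pol(th),
               tolerance = 1e-11)
  # smooth function: near machine accuracy already at M = 15
  d15 <- cheb_disc(15, 1)
  th2 <- seq(-1, 0, length.out = 101)
  expect_lt(max(abs(interp_eval(exp(d15$nodes), d15, th2) - exp(th2))), 1e-10)
  expect_error(interp_eval(vals, disc, 0.5), "outside")
})

test_that("the reduced system vanishes exactly at discretised equilibria", {
  cfg <- cfg_fixed()
  eq <- positive_equilibrium(cfg)
  disc <- cheb_disc(10, 2 * eq$tau_eq)
  sys <- ps_system(cfg, disc)
  u_eq <- discrete_equilibrium(eq, disc)
  expect_lt(max(abs(assemble_rhs(u_eq, sys))), 1e-10)
  u_tr <- discrete_equilibrium(trivial_equilibrium(cfg), disc)
  expect_equal(assemble_rhs(u_tr, sys), rep(0, 22))
  # perturbing a single node breaks the equilibrium property
  u_p <- u_eq; u_p[15] <- u_p[15] + 1e-3
  expect_gt(max(abs(assemble_rhs(u_p, sys))), 1e-5)
  # constant non-equilibrium data: differentiation rows vanish, the first
  # rows reproduce the functional at the constant history
  u_c <- c(rep(2, 11), rep(0.3, 11))
  rhs_c <- assemble_rhs(u_c, sys)
  Fc <- rhs_F(history_pair(2, 0.3, disc$h), cfg)
  expect_equal(rhs_c[c(1, 12)], Fc, tolerance = 1e-12)
  expect_lt(max(abs(rhs_c[-c(1, 12)])), 1e-12)
})

test_that("trivial-equilibrium eigenvalues reproduce the analytic roots", {
  set.seed(21)
  for (i in 1:6) {
    cfg <- scenario(sample(c("(s)_d", "(s)_s"), 1), p = runif(1, 0.3, 3),
                    mu = runif(1, 0.3, 2), g0 = runif(1, 0.1, 0.6))
    sp <- ps_eigenvalues(cfg, trivial_equilibrium(cfg), M = 15)
    zs <- complex(real = sp$re, imaginary = sp$im)
    expect_lt(min(abs(zs - q_rate(0, cfg$stem))), 1e-8)
    expect_lt(min(abs(zs + cfg$stem$mu)), 1e-8)
  }
})

test_that("eigenvalues converge spectrally to exact boundary roots", {
  cb <- cfg_on_boundary(2.5, 1.3)
  eq <- positive_equilibrium(cb$cfg)
  z_exact <- complex(imaginary = cb$prm$omega_unscaled)
  errs <- vapply(c(5, 10, 15, 20), function(M) {
    sp <- ps_eigenvalues(cb$cfg, eq, M = M)
    min(abs(complex(real = sp$re, imaginary = sp$im) - z_exact))
  }, numeric(1))
  # decay down to the rounding floor, superpolynomial in M
  expect_true(all(diff(errs) < 1e-8))
  expect_lt(errs[2], 1e-2 * errs[1])
  expect_lt(errs[4], 1e-2 * errs[2])
  expect_lt(errs[3], 1e-6)       # conjugate pair within 1e-6 at M = 15
})

test_that("the physical filter separates persistent from spurious modes", {
  cfg <- cfg_eta15(p = 6, mu = 2)
  sp <- ps_eigenvalues(cfg, M = 12, filter = TRUE)
  expect_true(sp$physical[1])              # rightmost root is physical
  expect_true(any(!sp$physical))           # some artifacts flagged
  g <- glance(sp)
  expect_equal(g$n_physical, sum(sp$physical))
  expect_identical(g$stable, sp$re[1] < 0)
})

test_that("stability verdicts agree with the analytic region on a grid", {
  # constant-g family, eta = 1.5: compare rightmost-eigenvalue sign with the
  # closed-form boundary on a small (mu, p) grid
  probe <- cfg_eta15()
  for (mu in c(1.8, 3, 5)) {
    p_bound <- analytic_crossing_p(mu, probe)$p
    for (p in c(0.8, 1.25) * p_bound) {
      cfg <- cfg_eta15(p = p, mu = mu)
      sp <- ps_eigenvalues(cfg, M = 10)
      expect_equal(sp$re[1] < 0, p < p_bound)
    }
  }
})

test_that("the reduced ODE path shadows the delay-system integration", {
  cfg <- cfg_eta15(p = 5, mu = 2)
  eq <- positive_equilibrium(cfg)
  h <- 2 * eq$tau_eq
  sol <- integrate_sdde(history_pair(1.05 * eq$w, 1.05 * eq$v, h), cfg,
                        t_end = 10, dt = 0.02)
  disc <- cheb_disc(15, h)
  sys <- ps_system(cfg, disc)
  u0 <- c(rep(1.05 * eq$w, 16), rep(1.05 * eq$v, 16))
  ps <- ps_integrate(sys, u0, t_end = 10, n_out = 41,
                     rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(ps$v - sol$v_fun(ps$t))), 1e-4)
  expect_lt(max(abs(ps$w - sol$w_fun(ps$t))), 1e-4)
})
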