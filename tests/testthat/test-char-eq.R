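test_that("trivial-equilibrium characteristic function factorises", {
  cfg <- cfg_fixed()          # q(0) = 0.6, mu = 1
  expect_equal(Mod(chi_trivial(0.6, cfg)), 0)
  expect_equal(Mod(chi_trivial(-1, cfg)), 0)
  expect_equal(Mod(chi_trivial(0, cfg)), 0.6)
})

test_that("characteristic function obeys basic identities", {
  cfg <- cfg_eta15(p = 6, mu = 2)
  ctx <- char_context(cfg)
  dv <- rate_derivatives(cfg)
  # value at the origin
  expect_equal(chi(0 + 0i, ctx),
               as.complex(cfg$stem$mu * ctx$v * dv$qp(ctx$v)),
               tolerance = 1e-12)
  # real coefficients: conjugate symmetry
  set.seed(7)
  zs <- complex(real = rnorm(10), imaginary = rnorm(10))
  expect_equal(chi(Conj(zs), ctx), Conj(chi(zs, ctx)), tolerance = 1e-12)
})

test_that("the simplified cascade collapses consistently", {
  cfg <- cfg_eta15(p = 6, mu = 2)
  set.seed(11)
  zs <- complex(real = rnorm(20), imaginary = rnorm(20))
  # full kernel form reduces to the constant-g closed form
  expect_lt(max(abs(chi(zs, char_context(cfg)) -
                    chi_simplified(zs, cfg, "b"))), 1e-10)
  expect_lt(max(abs(chi_simplified(zs, cfg, "b") -
                    chi_simplified(zs, cfg, "c"))), 1e-11)
  expect_lt(max(abs(chi_simplified(zs, cfg, "c") -
                    chi_simplified(zs, cfg, "d"))), 1e-11)
  # the last reduction flips the overall sign (roots unchanged)
  expect_lt(max(abs(chi_simplified(zs, cfg, "d") +
                    chi_simplified(zs, cfg, "e"))), 1e-12)
  # leading coefficient of the final form
  expect_equal(1 - 1 / ((2 * 0.9 - 1) * 2), 0.375)
  # hypotheses are enforced
  expect_error(chi_simplified(1 + 0i, scenario("(s)_s,(pv)_0,(px)_1"), "e"),
               "k_a = 0")
  expect_error(chi_simplified(1 + 0i, scenario("(s)_d,(pv)_1"), "b"),
               "constant")
})

test_that("the distributed kernel vanishes exactly in the fixed-delay case", {
  ctx <- char_context(cfg_fixed(p = 2))
  expect_true(ctx$kernel_zero)
  expect_equal(kernel_k(seq(0, ctx$tau, length.out = 9), ctx), rep(0, 9))
  expect_error(kernel_k(ctx$tau + 0.5, ctx), "outside")
})

test_that("the kernel matches an independent nested-quadrature evaluation", {
  # v- and x-dependent maturation: all three kernel terms are active
  cfg <- scenario("(s)_d,(pv)_1,(px)_1,quadratic", g0 = 0.3, p = 2)
  eq <- positive_equilibrium(cfg)
  ctx <- char_context(cfg, eq)
  v <- eq$v; tau <- eq$tau_eq
  dv <- rate_derivatives(cfg)
  mat <- cfg$mat
  # independent route: y by inverting s(y) = int_y^{x2} dx/g, every integral
  # by adaptive quadrature, no shared code with the context construction
  s_of_y <- function(y) stats::integrate(function(x) 1 / g_rate(x, v, mat),
                                         y, mat$x2, rel.tol = 1e-12)$value
  y_of_s <- function(s) stats::uniroot(function(y) s_of_y(y) - s,
                                       c(mat$x1, mat$x2), tol = 1e-13)$root
  QI <- function(t1, t2) stats::integrate(function(th) {
    vapply(th, function(u) dv$D1g(y_of_s(u), v), numeric(1))
  }, t1, t2, rel.tol = 1e-10)$value
  kern_oracle <- function(t) {
    yt <- y_of_s(t)
    term1 <- -dv$D2D1g(yt, v)
    term2 <- (-dv$D1g(mat$x1, v) / g_rate(mat$x1, v, mat)) *
      exp(-QI(t, tau)) * dv$D2g(yt, v)
    term3 <- dv$D2g(yt, v) * stats::integrate(function(sg) {
      vapply(sg, function(u) -dv$D1D1g(y_of_s(u), v) * exp(-QI(t, u)),
             numeric(1))
    }, t, tau, rel.tol = 1e-9)$value
    cfg$stem$mu * v * (term1 - term2 - term3)
  }
  for (t in c(0.25 * tau, 0.5 * tau, 0.8 * tau)) {
    ko <- kern_oracle(t)
    expect_equal(kernel_k(t, ctx), ko, tolerance = 1e-7 * max(1, abs(ko)))
  }
})

test_that("characteristic roots are located by the argument principle", {
  cfg <- cfg_fixed()
  # trivial equilibrium: exactly the two analytic roots
  fr <- find_roots(function(z) chi_trivial(z, cfg), re = c(-2.3, 1.4),
                   im_max = 1)
  expect_equal(nrow(fr), 2)
  expect_equal(sort(fr$re), c(-1, 0.6), tolerance = 1e-10)
  expect_equal(fr$im, c(0, 0), tolerance = 1e-10)
  expect_true(all(fr$residual < 1e-10))
  # the default wrapper finds the same set
  fr2 <- char_roots(cfg, "trivial")
  expect_equal(sort(fr2$re), c(-1, 0.6), tolerance = 1e-10)
})

test_that("the positive equilibrium is stable upon emergence", {
  # just above the transcritical point: a single small negative real root
  p_star <- 1.25
  cfg <- cfg_fixed(p = 1.02 * p_star)
  ctx <- char_context(cfg)
  fr <- find_roots(function(z) chi(z, ctx), re = c(-0.3, 0.3), im_max = 0.4)
  expect_equal(nrow(fr), 1)
  expect_lt(fr$re[1], 0)
  expect_equal(fr$im[1], 0, tolerance = 1e-10)
  # the root moves like q'(0) v near the bifurcation
  dv <- rate_derivatives(cfg)
  v <- ctx$v
  expect_equal(fr$re[1] / v, dv$qp(0), tolerance = 0.1)
  # no roots in the right half-plane nearby (scan certificate)
  fr_rhp <- find_roots(function(z) chi(z, ctx), re = c(1e-4, 3), im_max = 8)
  expect_equal(nrow(fr_rhp), 0)
})

test_that("a conjugate pair sits on the axis at analytic boundary points", {
  cb <- cfg_on_boundary(1.5, 1.9)
  z <- complex(imaginary = cb$prm$omega_unscaled)
  expect_lt(abs(chi_simplified(z, cb$cfg, "e")), 1e-10)
  expect_lt(abs(chi(z, char_context(cb$cfg))), 1e-8)
  fr <- find_roots(function(z) chi_simplified(z, cb$cfg, "e"),
                   re = c(-1.4, 0.8), im_max = 3)
  onaxis <- fr[abs(fr$im) > 0.1, ]
  expect_equal(nrow(onaxis), 2)
  expect_true(all(abs(onaxis$re) < 1e-6))
  expect_equal(sort(onaxis$im), c(-1, 1) * cb$prm$omega_unscaled,
               tolerance = 1e-8)
})
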