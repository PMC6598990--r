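test_that("stem-cell net growth and inflow rates match the regulated forms", {
  sp <- stem_params(mu = 1, mu_w = 1, a = 0.9, p = 2, k_a = 0, k_p = 0)
  expect_equal(q_rate(0, sp), (2 * 0.9 - 1) * 2 - 1)     # 0.6
  expect_equal(gamma_rate(0, sp), 2 * (1 - 0.9) * 2)     # 0.4
  # without division the net growth is pure mortality and no inflow occurs
  sp0 <- stem_params(mu = 1, mu_w = 1, a = 0.9, p = 0)
  expect_equal(q_rate(c(0, 0.7, 3), sp0), rep(-1, 3))
  expect_equal(gamma_rate(c(0, 0.7, 3), sp0), rep(0, 3))
  # regulated division: q crosses zero at v = (2a-1)p/mu_w - 1 = 0.6
  spd <- stem_params(mu = 1, mu_w = 1, a = 0.9, p = 2, k_a = 0, k_p = 1)
  v_root <- (2 * 0.9 - 1) * 2 / 1 - 1
  expect_equal(v_root, 0.6)
  expect_equal(q_rate(v_root, spd), 0)
  expect_equal(gamma_rate(0.6, spd), 2 * (1 - 0.9) * 2 / 1.6)  # 0.25
  expect_error(q_rate(-0.1, spd), "nonnegative")
  expect_error(gamma_rate(-1, spd), "nonnegative")
})

test_that("maturation rate evaluates the baseline-plus-regulation form", {
  m1 <- maturation_params(g0 = 0, k1 = 0, k2 = 0, a_u = 1 / 3, p_u = 0.3)
  expect_equal(g_rate(0.5, 0, m1), 0.4)
  expect_equal(g_rate(c(0, 1), 7, m1), c(0.4, 0.4))       # constant in x and v
  m2 <- maturation_params(g0 = 1, k1 = 0, k2 = 0, a_u = 0.5, p_u = 0)
  expect_equal(g_rate(0.3, 2, m2), 1)
  # strong feedback through k1 suppresses the regulated part towards g0
  m3 <- maturation_params(g0 = 0.7, k1 = 1, k2 = 0, a_u = 1 / 3, p_u = 0.3)
  expect_equal(g_rate(0.5, 1e8, m3), 0.7, tolerance = 1e-6)
  expect_error(g_rate(0.5, -1, m3), "nonnegative")
  expect_error(g_rate(2, 0, m3), "maturity")
  # nonpositive g is rejected at construction
  expect_error(maturation_params(g0 = 0, a_u = 2, p_u = 0.3), "not positive")
})

test_that("default progenitor production is zero, custom profiles plug in", {
  cfg <- cfg_fixed()
  expect_equal(d_rate(c(0, 0.4, 1), 0.3, cfg), c(0, 0, 0))
  dv <- rate_derivatives(cfg)
  expect_equal(dv$D1d(0.5, 0.3), 0)
  expect_equal(dv$D2d(0.5, 0.3), 0)
  cfg2 <- model_config(cfg$stem, cfg$mat,
                       d = list(fun = function(x, v) rep(0.25, length(x))))
  expect_equal(d_rate(0.5, 0.3, cfg2), 0.25)
})

test_that("named scenarios resolve to the documented parameter sets", {
  c1 <- scenario("(s)_d,(pv)_0")
  expect_equal(c(c1$stem$k_a, c1$stem$k_p), c(0, 1))
  expect_equal(c(c1$mat$k1, c1$mat$k2), c(0, 0))
  c2 <- scenario("(s)_s,(pv)_2")
  expect_equal(c(c2$stem$k_a, c2$stem$k_p), c(1, 0))
  expect_equal(c(c2$mat$k1, c2$mat$k2), c(0, 1))
  # fixed baseline of the numerical study
  expect_equal(c(c1$mat$x1, c1$mat$x2, c1$stem$mu_w, c1$stem$a),
               c(0, 1, 1, 0.9))
  # quadratic maturity profile of the first x-dependent family
  c3 <- scenario("(px)_1,quadratic")
  xg <- c(0, 0.25, 0.5, 1)
  expect_equal(c3$mat$a_u$fun(xg), 0.1 + 2.8 * (xg - 0.5)^2)
  expect_equal(c3$mat$p_u$fun(xg), rep(0.3, 4))
  c4 <- scenario("(px)_2,linear", p = 2)
  expect_equal(c4$mat$a_u$fun(xg), 0.99 - 0.18 * xg)
  expect_equal(c4$mat$p_u$fun(0.3), 2)
  expect_error(scenario("(s)_q"), "unknown scenario")
  expect_error(scenario("(s)_s,(s)_d"), "conflicting")
})

test_that("closed-form derivatives agree with central differences", {
  fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  # division-regulated family: q'(v) = -(2a-1) p / (1+v)^2
  spd <- stem_params(a = 0.9, p = 2, k_a = 0, k_p = 1)
  dv <- rate_derivatives(model_config(spd, cfg_fixed()$mat))
  expect_equal(dv$qp(0.4), -(2 * 0.9 - 1) * 2 / 1.4^2, tolerance = 1e-12)
  # self-renewal-regulated family at v = 0: gamma'(0) = 2 a p
  sps <- stem_params(a = 0.9, p = 2, k_a = 1, k_p = 0)
  dvs <- rate_derivatives(model_config(sps, cfg_fixed()$mat))
  expect_equal(dvs$gammap(0), 3.6, tolerance = 1e-12)
  expect_equal(dvs$gammap(0.5),
               fd(function(v) gamma_rate(v, sps), 0.5), tolerance = 1e-6)
  # random parameter draws across the built-in families
  set.seed(42)
  for (i in 1:100) {
    st <- stem_params(mu = runif(1, 0.2, 3), mu_w = runif(1, 0, 2),
                      a = runif(1, 0.55, 0.95), p = runif(1, 0.3, 3),
                      k_a = runif(1, 0, 2), k_p = runif(1, 0, 2))
    shape <- sample(c("constant", "linear", "quadratic"), 1)
    mt <- scenario(paste0("(s)_d,(px)_1,", shape), g0 = runif(1, 0, 1))$mat
    mt$k1 <- runif(1, 0, 1.5); mt$k2 <- runif(1, 0, 1.5)
    cfg <- model_config(st, mt, h = 100)
    dv <- rate_derivatives(cfg)
    v <- runif(1, 0.01, 3); x <- runif(1, 0, 1)
    rel <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))
    expect_lt(rel(dv$qp(v), fd(function(v) q_rate(v, st), v)), 1e-6)
    expect_lt(rel(dv$gammap(v), fd(function(v) gamma_rate(v, st), v)), 1e-6)
    expect_lt(rel(dv$D1g(x, v),
                  fd(function(x) g_rate(x, v, mt, x_tol = 0.1), x)), 1e-6)
    expect_lt(rel(dv$D2g(x, v),
                  fd(function(v) g_rate(x, v, mt), v)), 1e-6)
    expect_lt(rel(dv$D2D1g(x, v),
                  fd(function(v) dv$D1g(x, v), v)), 1e-6)
    expect_lt(rel(dv$D1D1g(x, v),
                  fd(function(x) dv$D1g(x, v), x)), 1e-6)
  }
})

test_that("regulated net growth decreases monotonically to a negative value", {
  for (lbl in c("(s)_s", "(s)_d")) {
    st <- scenario(lbl)$stem
    vg <- seq(0, 50, length.out = 400)
    qv <- q_rate(vg, st)
    expect_true(all(diff(qv) < 0))
    expect_lt(qv[length(qv)], 0)
    # self-renewal fraction and division rate stay in (0, a] and (0, p]
    expect_true(all(s_frac(vg, st) > 0 & s_frac(vg, st) <= st$a))
    expect_true(all(dw_rate(vg, st) > 0 & dw_rate(vg, st) <= st$p))
  }
})
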