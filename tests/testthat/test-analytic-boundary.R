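test_that("trigonometric auxiliaries take their special values", {
  for (eta in c(0.5, 1.5, 2.5)) {
    expect_equal(f_eta(pi / 2, eta), eta)
    expect_equal(f_eta(2 * pi, eta), -2 * pi)
    expect_equal(f_eta(4 * pi, eta), -4 * pi)
    expect_equal(f_eta(3 * pi / 2, eta), -eta)
    expect_equal(g_eta(0, eta), eta)
    expect_equal(g_eta(pi / 2, eta), pi / 2)
    expect_equal(g_eta(5 * pi / 2, eta), 5 * pi / 2)
    expect_equal(g_eta(pi, eta), -eta)
  }
})

test_that("boundary points satisfy the two real crossing equations", {
  eta <- 1.5
  bc <- boundary_curve(eta, n_points = 60)
  expect_true(all(bc$m > 0))
  expect_true(all(bc$r > 0))
  for (i in seq(1, 60, by = 7)) {
    H <- sddcell:::H_equations(bc$m[i], bc$r[i], 0, bc$omega[i], eta)
    expect_lt(max(abs(H)), 1e-10)
  }
  # explicit point: at omega = pi/2 the parametrisation gives (eta, pi/(2 eta))
  bp <- boundary_point(pi / 2, eta)
  expect_equal(bp$m, eta)
  expect_equal(bp$r, pi / (2 * eta))
  expect_error(boundary_point(0, eta), "singularity")
})

test_that("singularities follow the documented interval catalogue", {
  s15 <- singularities(1.5, count = 4)
  expect_equal(s15$omega[1], 0)
  for (j in 1:4) {
    expect_gt(s15$omega[j + 1], pi / 2 + (j - 1) * pi / 2)
    expect_lt(s15$omega[j + 1], pi + (j - 1) * pi / 2)
  }
  s05 <- singularities(0.5, count = 4)
  for (j in 1:4) {
    expect_gt(s05$omega[j + 1], (j - 1) * pi / 2)
    expect_lt(s05$omega[j + 1], pi / 2 + (j - 1) * pi / 2)
  }
  # the function that vanishes alternates consistently: f then g for eta < 1
  expect_equal(s05$vanishing[2:5], c("f", "g", "f", "g"))
  # first zero for eta = 0.5 solves tan(omega) = 2 omega
  om1 <- s05$omega[2]
  expect_equal(tan(om1), 2 * om1, tolerance = 1e-9)
  expect_equal(om1, 1.16556, tolerance = 1e-5)
  # zeros refined to the stated accuracy
  expect_lt(abs(f_eta(om1, 0.5)), 1e-11)
})

test_that("boundary limits match the asymptotic catalogue", {
  # eta > 1: the curve starts at (m, r) = (0, 1/(eta - 1))
  bc <- boundary_curve(1.5, n_points = 400, margin = 1e-8)
  expect_equal(bc$r[1], 1 / (1.5 - 1), tolerance = 1e-6)
  expect_lt(bc$m[1], 1e-6)
  expect_gt(bc$m[400], 1e4)                      # m blows up at omega_1^-
  # eta < 1: r -> +Inf and m -> 0 at the left end of the window
  bc2 <- boundary_curve(0.5, n_points = 400, margin = 1e-8)
  expect_gt(bc2$r[1], 1e4)
  expect_lt(bc2$m[1], 1e-4)
  expect_gt(bc2$m[400], 1e4)
})

test_that("m increases along the boundary and crossings point rightward", {
  for (eta in c(0.5, 0.99, 1.5, 2.5, 4)) {
    bc <- boundary_curve(eta, n_points = 300, margin = 1e-5)
    expect_true(all(diff(bc$m) > 0))
    expect_true(all(bc$det_H < 0))
  }
})

test_that("the crossing determinant matches its finite-difference oracle", {
  set.seed(5)
  for (i in 1:50) {
    m <- runif(1, 0.1, 5); r <- runif(1, 0.1, 3)
    om <- runif(1, 0.1, 6); eta <- runif(1, 0.2, 4)
    Hm <- function(mm, rr, nu, oo) sddcell:::H_equations(mm, rr, nu, oo, eta)
    h <- 1e-6
    # Jacobian of (H1, H2) with respect to (m, r) at nu = 0
    J <- cbind((Hm(m + h, r, 0, om) - Hm(m - h, r, 0, om)) / (2 * h),
               (Hm(m, r + h, 0, om) - Hm(m, r - h, 0, om)) / (2 * h))
    expect_equal(det(J), det_H(m, r, om, eta),
                 tolerance = 1e-6 * max(1, abs(det(J))))
  }
})

test_that("boundary shape classification reproduces the threshold pattern", {
  c05 <- classify_shape(0.5)
  expect_equal(c05$shape, "non-monotone-with-minimum")
  expect_equal(c05$minimiser_location, "omega>pi/2")
  c25 <- classify_shape(2.5)
  expect_equal(c25$shape, "non-monotone-with-minimum")
  expect_equal(c25$minimiser_location, "omega<pi/2")
  c40 <- classify_shape(4)
  expect_equal(c40$shape, "monotone-increasing")
  expect_equal(classify_shape(3.2)$shape, "monotone-increasing")
  expect_equal(classify_shape(2.8)$shape, "non-monotone-with-minimum")
})

test_that("unscaling maps the boundary into the mortality/division plane", {
  expect_equal(to_mu_p(0, 0, tau = 2, mu_w = 1, a = 0.9)$p, 1.25)
  expect_gt(to_mu_p(1, 1 - 1e-12, tau = 1)$p, 1e10)
  expect_error(to_mu_p(1, 1, tau = 1), "r >= 1")
  # eta = tau = mu_w = 1: m and mu coincide
  expect_equal(to_mu_p(0.7, 0.3, tau = 1, mu_w = 1)$mu, 0.7)
})
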