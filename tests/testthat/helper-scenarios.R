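# Shared fixtures: configurations used across several test files.

# constant maturation rate g = 0.4 (fixed delay tau = 2.5, eta = 2.5)
cfg_fixed <- function(p = 2, mu = 1, g0 = 0) {
  scenario("(s)_d,(pv)_0,(px)_1", p = p, mu = mu, g0 = g0)
}

# fixed-delay family with tau = 1.5 (eta = 1.5): g = g0 + 0.4 = 2/3
cfg_eta15 <- function(p = 2, mu = 1) {
  scenario("(s)_d,(pv)_0,(px)_1", p = p, mu = mu, g0 = 2 / 3 - 0.4)
}

# a parameter point exactly on the analytic stability boundary for a given
# eta (tau = eta since mu_w = 1); omega is the scaled crossing frequency
boundary_params <- function(eta, omega) {
  bp <- boundary_point(omega, eta)
  up <- to_mu_p(bp$m, bp$r, tau = eta, mu_w = 1, a = 0.9)
  list(mu = up$mu, p = up$p, tau = eta, omega_unscaled = omega / eta,
       m = bp$m, r = bp$r)
}

# configuration on the analytic boundary (constant g chosen so tau = eta)
cfg_on_boundary <- function(eta, omega) {
  prm <- boundary_params(eta, omega)
  list(cfg = scenario("(s)_d,(pv)_0,(px)_1", g0 = 1 / eta - 0.4,
                      p = prm$p, mu = prm$mu),
       prm = prm)
}
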