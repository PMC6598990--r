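# Trivial and positive equilibria, the existence condition and the
# transcritical threshold.

#' Trivial equilibrium
#'
#' The extinction state `(w, v) = (0, 0)`.  It always exists; it is stable
#' when `q(0) < 0` and destabilised by the positive equilibrium when
#' `q(0) > 0`.
#'
#' @param cfg A [model_config()] object (used only for the delay at the
#'   constant zero history).
#' @return An object of class `equilibrium`.
#' @export
trivial_equilibrium <- function(cfg) {
  new_equilibrium(w = 0, v = 0, kind = "trivial", residual = 0,
                  tau_eq = tau_constant_history(0, cfg))
}

new_equilibrium <- function(w, v, kind, residual, tau_eq) {
  structure(list(w = w, v = v, kind = kind, residual = residual,
                 tau_eq = tau_eq), class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium: w = %.10g, v = %.10g  (tau = %.8g, residual %.2e)\n",
              x$kind, x$w, x$v, x$tau_eq, x$residual))
  invisible(x)
}

#' Transcritical threshold of the division rate
#'
#' The positive equilibrium exists if and only if `q(0) > 0`, i.e.
#' `p > mu_w / (2a - 1)`.  At the threshold the positive equilibrium merges
#' with the trivial one and the two exchange stability.
#'
#' @param stem A [stem_params()] object (or a [model_config()], whose stem
#'   component is used).
#' @return The critical division rate `p* = mu_w / (2a - 1)`.
#' @examples
#' existence_threshold(stem_params(mu_w = 1, a = 0.9))  # 1.25
#' @export
existence_threshold <- function(stem) {
  if (inherits(stem, "model_config")) stem <- stem$stem
  stopifnot(inherits(stem, "stem_params"))
  stem$mu_w / (2 * stem$a - 1)
}

#' Positive equilibrium
#'
#' Solves the equilibrium conditions: `v` is the root of `q(v) = 0`
#' (bracketed by doubling, then polished with Brent's method), and
#' `w = mu v g(x1, v) / (gamma(v) g(x2, v)) * exp(-I)` with
#' `I = int_0^{tau(v)} (d - D1g)(y(s, v), v) ds` evaluated along the
#' constant-history maturity trajectory.  The exponential correction uses
#' the same quadrature as the right-hand-side functional, so the returned
#' residual `|F(w, v)|` is a genuine certificate.
#'
#' @param cfg A [model_config()] object with `q(0) > 0`.
#' @param v_cap Bracketing cap for the root of `q` (default `1e6`).
#' @return An object of class `equilibrium` with `kind = "positive"`.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0,(px)_1")   # k_a = 0, k_p = 1, g = 0.4
#' positive_equilibrium(cfg)                # v = 0.6, w = 2.4
#' @export
positive_equilibrium <- function(cfg, v_cap = 1e6) {
  stem <- cfg$stem
  q0 <- q_rate(0, stem)
  if (q0 <= 0) {
    stop("no positive equilibrium: q(0) = ", format(q0),
         " <= 0 (p below the transcritical threshold ",
         format(existence_threshold(stem)), ")")
  }
  hi <- 1
  while (q_rate(hi, stem) > 0) {
    hi <- 2 * hi
    if (hi > v_cap) stop("could not bracket the root of q below v = ", v_cap)
  }
  v <- stats::uniroot(function(v) q_rate(v, stem), c(0, hi),
                      f.lower = q0, tol = 1e-15)$root
  traj <- maturity_trajectory(v, cfg, h = 2.5 * tau_constant_history(v, cfg),
                              with_integral = TRUE)
  mat <- cfg$mat
  w <- stem$mu * v * g_rate(mat$x1, v, mat) /
    (gamma_rate(v, stem) * g_rate(mat$x2, v, mat)) * exp(-traj$exp_integral)
  res <- sqrt(sum(rhs_F(history_pair(w, v, h = 2.5 * traj$tau), cfg)^2))
  new_equilibrium(w = w, v = v, kind = "positive", residual = res,
                  tau_eq = traj$tau)
}

#' @rdname sddcell-tidiers
#' @export
tidy.equilibrium <- function(x, ...) {
  tibble::tibble(kind = x$kind, w = x$w, v = x$v,
                 tau = x$tau_eq, residual = x$residual)
}
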