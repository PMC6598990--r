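# Closed-form stability boundary for the fixed-delay special case
# (constant maturation rate, unregulated self-renewal): scaled characteristic
# equation r m (lambda + eta) e^{-lambda} + lambda^2 + m lambda = 0 in the
# scaled coordinates m = mu * tau, r = 1 - mu_w / ((2a - 1) p), eta = mu_w * tau.

#' Trigonometric auxiliaries of the scaled boundary
#'
#' `f_eta(omega) = eta sin(omega) - omega cos(omega)` and
#' `g_eta(omega) = omega sin(omega) + eta cos(omega)`; their zeros are the
#' singularities of the boundary parametrisation.
#'
#' @param omega Nonnegative frequency (imaginary part of the scaled root);
#'   vectorised.
#' @param eta Scaled stem-cell mortality `mu_w * tau` (> 0).
#' @return Numeric vector.
#' @examples
#' f_eta(pi / 2, 1.5)   # equals eta
#' g_eta(0, 1.5)        # equals eta
#' @export
f_eta <- function(omega, eta) eta * sin(omega) - omega * cos(omega)

#' @rdname f_eta
#' @export
g_eta <- function(omega, eta) omega * sin(omega) + eta * cos(omega)

#' Boundary point in scaled coordinates
#'
#' For a root `lambda = i omega` on the imaginary axis, the scaled
#' characteristic equation splits into two real equations whose solution is
#' `r = omega / f_eta(omega)` and `m = omega f_eta(omega) / g_eta(omega)`.
#'
#' @param omega Frequency at the crossing (> 0, away from singularities).
#' @param eta Scaled stem-cell mortality.
#' @param tol Singularity tolerance on `|f_eta|`, `|g_eta|`.
#' @return A list with `m` and `r` (vectorised over `omega`).
#' @export
boundary_point <- function(omega, eta, tol = 1e-12) {
  fe <- f_eta(omega, eta); ge <- g_eta(omega, eta)
  if (any(abs(fe) < tol) || any(abs(ge) < tol)) {
    stop("omega too close to a singularity of the boundary parametrisation")
  }
  list(m = omega * fe / ge, r = omega / fe)
}

#' Singularities of the boundary parametrisation
#'
#' Returns the ordered singular frequencies `omega_0 = 0 < omega_1 < ...`:
#' the zeros of `f_eta` and `g_eta`.  For `eta >= 1` the j-th singularity
#' lies in `(pi/2, pi) + (j - 1) pi/2`; for `eta < 1` in
#' `(0, pi/2) + (j - 1) pi/2`.  Each is refined by Brent bisection to
#' `1e-12`; the function that vanishes there is recorded.
#'
#' @param eta Scaled stem-cell mortality (> 0).
#' @param count Number of nonzero singularities to return.
#' @return Tibble with columns `j`, `omega`, `vanishing` (`"f"` or `"g"`).
#' @export
singularities <- function(eta, count = 4) {
  stopifnot(eta > 0, count >= 1)
  out <- vector("list", count)
  for (j in seq_len(count)) {
    base <- (j - 1) * pi / 2
    intv <- if (eta >= 1) base + c(pi / 2, pi) else base + c(0, pi / 2)
    lo <- intv[1] + 1e-11; hi <- intv[2] - 1e-11
    flo <- f_eta(lo, eta); fhi <- f_eta(hi, eta)
    if (flo * fhi < 0) {
      fn <- "f"; root <- stats::uniroot(f_eta, c(lo, hi), eta = eta,
                                        f.lower = flo, f.upper = fhi,
                                        tol = 1e-13)$root
    } else {
      glo <- g_eta(lo, eta); ghi <- g_eta(hi, eta)
      if (glo * ghi >= 0) {
        stop("bracketing failure for singularity ", j, " at eta = ", eta)
      }
      fn <- "g"; root <- stats::uniroot(g_eta, c(lo, hi), eta = eta,
                                        f.lower = glo, f.upper = ghi,
                                        tol = 1e-13)$root
    }
    out[[j]] <- tibble::tibble(j = j, omega = root, vanishing = fn)
  }
  rbind(tibble::tibble(j = 0L, omega = 0, vanishing = NA_character_),
        do.call(rbind, out))
}

# parametrisation interval of the stability boundary (open)
boundary_interval <- function(eta) {
  sing <- singularities(eta, count = 2)
  if (eta >= 1) c(0, sing$omega[sing$j == 1]) else
    c(sing$omega[sing$j == 1], sing$omega[sing$j == 2])
}

#' Sampled analytic stability boundary
#'
#' Samples the boundary `omega -> (m, r)(omega)` on its parametrisation
#' interval: `(0, omega_1)` for `eta >= 1` and `(omega_1, omega_2)` for
#' `eta < 1`, excluding a margin around the singular endpoints.  If `tau`,
#' `mu_w` and `a` are supplied, the points are also mapped to the
#' `(mu, p)` plane via `mu = m / tau`, `p = mu_w / ((2a - 1)(1 - r))`.
#'
#' @param eta Scaled stem-cell mortality (> 0).
#' @param n_points Number of sampled points.
#' @param tau,mu_w,a Optional unscaling parameters.
#' @param margin Open-interval exclusion margin near the singularities.
#' @return Tibble of class `boundary_curve` with columns `omega`, `m`, `r`,
#'   `det_H` and, when unscaling parameters are given, `mu`, `p`.
#' @examples
#' bc <- boundary_curve(1.5, n_points = 5)
#' bc$r[1]   # near 1/(eta - 1) = 2 for small omega
#' @export
boundary_curve <- function(eta, n_points = 200, tau = NULL, mu_w = 1, a = 0.9,
                           margin = 1e-6) {
  iv <- boundary_interval(eta)
  om <- seq(iv[1] + margin, iv[2] - margin, length.out = n_points)
  bp <- boundary_point(om, eta)
  out <- tibble::tibble(omega = om, m = bp$m, r = bp$r,
                        det_H = det_H(bp$m, bp$r, om, eta))
  if (!is.null(tau)) {
    out$mu <- out$m / tau
    # points with r >= 1 lie outside the existence region: no finite p
    out$p <- ifelse(out$r < 1,
                    mu_w / ((2 * a - 1) * (1 - pmin(out$r, 1 - 1e-300))),
                    NA_real_)
  }
  class(out) <- c("boundary_curve", class(out))
  attr(out, "eta") <- eta
  out
}

#' Crossing determinant
#'
#' The determinant of the Jacobian of the two real boundary equations with
#' respect to `(m, r)` at a purely imaginary root; in closed form
#' `-omega * m * (eta cos(omega) + omega sin(omega))`.  A negative value
#' certifies that a conjugate pair crosses into the right half-plane when
#' the boundary is traversed with increasing `omega`.
#'
#' @param m,r Scaled coordinates.
#' @param omega Crossing frequency.
#' @param eta Scaled stem-cell mortality.
#' @return Numeric vector.
#' @export
det_H <- function(m, r, omega, eta) {
  -omega * m * g_eta(omega, eta)
}

# the two real equations at lambda = nu + i omega (used by tests as an
# independent route to the boundary)
H_equations <- function(m, r, nu, omega, eta) {
  c(H1 = nu^2 - omega^2 + m * nu +
      m * r * exp(-nu) * ((nu + eta) * cos(omega) + omega * sin(omega)),
    H2 = 2 * nu * omega + m * omega +
      m * r * exp(-nu) * (omega * cos(omega) - (nu + eta) * sin(omega)))
}

#' Shape classification of the stability boundary
#'
#' Classifies the boundary `m -> r(m)` (with `m` increasing along the
#' parametrisation): for `eta < 3` the curve first decreases and then
#' increases, with the minimum at `omega > pi/2` when `eta < pi^2/4`,
#' `omega = pi/2` when `eta = pi^2/4` and `omega < pi/2` when
#' `eta > pi^2/4`; for `eta >= 3` it is monotonically increasing.  The
#' classification is computed from the sign pattern of `dr/domega` on a
#' dense grid with bisection refinement; the analytic thresholds are then
#' recovered numerically by the tests, not assumed.
#'
#' @param eta Scaled stem-cell mortality (> 0).
#' @param n_grid Grid size for the sign scan.
#' @param margin Exclusion margin at the interval ends (the derivative
#'   vanishes at `omega = 0` by the series limit).
#' @param tol Tolerance used to resolve ties at the classification
#'   thresholds.
#' @return A list with `shape` (`"monotone-increasing"` or
#'   `"non-monotone-with-minimum"`), and for curves with a minimum the
#'   minimiser `omega_min`, its location category `minimiser_location`
#'   (relative to `pi/2`) and the coordinates `m_min`, `r_min`.
#' @export
classify_shape <- function(eta, n_grid = 2000, margin = NULL, tol = 1e-9) {
  iv <- boundary_interval(eta)
  if (is.null(margin)) margin <- 1e-4 * (iv[2] - iv[1])
  om <- seq(iv[1] + margin, iv[2] - margin, length.out = n_grid)
  dr <- drdomega(om, eta)
  if (all(dr >= -tol)) {
    return(list(shape = "monotone-increasing", omega_min = NA_real_,
                minimiser_location = NA_character_,
                m_min = NA_real_, r_min = NA_real_))
  }
  # refine the sign change closing the decreasing stretch
  idx <- which(dr[-length(dr)] < 0 & dr[-1] >= 0)
  if (length(idx) == 0) {
    # decreasing on the whole sampled grid: minimum pushed to the right end
    idx <- length(om) - 1
  }
  i <- idx[1]
  root <- stats::uniroot(function(o) drdomega(o, eta), c(om[i], om[i + 1]),
                         tol = 1e-12)$root
  bp <- boundary_point(root, eta)
  loc <- if (abs(root - pi / 2) <= tol) "omega=pi/2"
         else if (root > pi / 2) "omega>pi/2" else "omega<pi/2"
  list(shape = "non-monotone-with-minimum", omega_min = root,
       minimiser_location = loc, m_min = bp$m, r_min = bp$r)
}

#' Shape thresholds of the boundary family
#'
#' Recovers, by bisection on the scaled stem-cell mortality, the two
#' qualitative thresholds of the boundary family: `eta_monotone`, the
#' smallest value for which `r(m)` is monotonically increasing over the
#' whole parametrisation interval (no interior minimum), and
#' `eta_min_at_pi_half`, the value at which the interior minimiser sits
#' exactly at `omega = pi/2`.  Both are determined purely numerically from
#' the sign scan of `dr/domega` (see [classify_shape()]).
#'
#' @param tol Bisection tolerance on `eta`.
#' @param bracket_monotone,bracket_pi_half Search brackets.
#' @param n_grid Grid size for the sign scan.
#' @return A list with `eta_monotone` and `eta_min_at_pi_half`.
#' @examples
#' eta_shape_thresholds(tol = 1e-2)
#' @export
eta_shape_thresholds <- function(tol = 1e-3,
                                 bracket_monotone = c(1.5, 5),
                                 bracket_pi_half = c(1.2, 2.9),
                                 n_grid = 2000) {
  is_monotone <- function(eta) {
    classify_shape(eta, n_grid = n_grid)$shape == "monotone-increasing"
  }
  lo <- bracket_monotone[1]; hi <- bracket_monotone[2]
  if (is_monotone(lo) || !is_monotone(hi)) {
    stop("monotonicity bracket does not straddle the threshold")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_monotone(mid)) hi <- mid else lo <- mid
  }
  eta_monotone <- (lo + hi) / 2

  min_offset <- function(eta) classify_shape(eta, n_grid = n_grid)$omega_min - pi / 2
  lo2 <- bracket_pi_half[1]; hi2 <- bracket_pi_half[2]
  flo <- min_offset(lo2); fhi <- min_offset(hi2)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("minimiser bracket does not straddle pi/2")
  }
  while (hi2 - lo2 > tol) {
    mid <- (lo2 + hi2) / 2
    if (min_offset(mid) * flo > 0) { lo2 <- mid } else { hi2 <- mid }
  }
  list(eta_monotone = eta_monotone, eta_min_at_pi_half = (lo2 + hi2) / 2)
}

# derivative of r(omega) = omega / f_eta(omega) by central differences
drdomega <- function(omega, eta, step = 1e-6) {
  (omega + step) / f_eta(omega + step, eta) / (2 * step) -
    (omega - step) / f_eta(omega - step, eta) / (2 * step)
}

#' Map scaled boundary coordinates to the mortality/division plane
#'
#' Inverts the scaling: `mu = m / tau` and `p = mu_w / ((2a - 1)(1 - r))`.
#' At `r = 0` the boundary meets the transcritical (existence) line
#' `p = mu_w / (2a - 1)`; as `r -> 1` the division rate diverges.
#'
#' @param m,r Scaled coordinates (vectorised); requires `r < 1`.
#' @param tau Fixed delay (> 0).
#' @param mu_w Stem-cell mortality.
#' @param a Maximal self-renewal fraction (> 0.5).
#' @return A list with `mu` and `p`.
#' @export
to_mu_p <- function(m, r, tau, mu_w = 1, a = 0.9) {
  stopifnot(tau > 0)
  if (any(r >= 1)) stop("no finite division rate for r >= 1")
  list(mu = m / tau, p = mu_w / ((2 * a - 1) * (1 - r)))
}
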