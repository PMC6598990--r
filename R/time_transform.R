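# Time transformation to a fixed-delay system, available when the maturation
# rate is independent of maturity: the physiological-time reparametrisation
# Phi_f / T_f, the transformed functional G with fixed delay delta = x2 - x1,
# solution correspondence, and eigenvalue correspondence z <-> z / g(v).

require_x_independent <- function(cfg) {
  if (!g_is_x_independent(cfg$mat)) {
    stop("the time transformation requires a maturation rate independent of ",
         "maturity (constant a_u and p_u profiles)")
  }
  invisible(cfg)
}

# g as a function of v only (valid when x-independent)
g_of_v <- function(v, cfg, check = TRUE) {
  g_rate(cfg$mat$x1, v, cfg$mat, check = check)
}

#' Time transformations between original and physiological time
#'
#' `phi_transform()` maps original time to transformed (physiological) time:
#' `Phi_f(t)` is the signed integral of `g(f(theta))` from 0 to `t`, i.e. the
#' maturity distance travelled.  `t_transform()` is the inverse-direction
#' map: `T_f(phi)` is the signed integral of `1 / g(f(theta))`.  For matched
#' `f` the two are inverse bijections.  `tau_zeta()` returns
#' `-T_zeta(-delta)`, the threshold delay induced by a transformed history
#' `zeta` on `[-delta, 0]`.
#'
#' @param f Function (range in the admissible `v` domain) defined on an
#'   interval containing 0 and the evaluation points.
#' @param t,phi Evaluation points (vectorised).
#' @param cfg A [model_config()] with maturity-independent `g`.
#' @param zeta Transformed mature-cell history on `[-delta, 0]`.
#' @return Numeric vector of transformed times.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_1")
#' phi_transform(function(t) rep(0.5, length(t)), 2, cfg)  # 2 g(0.5)
#' @export
phi_transform <- function(f, t, cfg) {
  require_x_independent(cfg)
  gf <- function(theta) {
    gv <- g_of_v(f(theta), cfg)
    if (any(gv <= 0)) stop("maturation rate nonpositive along the path")
    gv
  }
  vapply(t, function(ti) {
    if (ti >= 0) gl_quad(gf, 0, ti, 48) else -gl_quad(gf, ti, 0, 48)
  }, numeric(1))
}

#' @rdname phi_transform
#' @export
t_transform <- function(f, phi, cfg) {
  require_x_independent(cfg)
  invg <- function(theta) {
    gv <- g_of_v(f(theta), cfg)
    if (any(gv <= 0)) stop("maturation rate nonpositive along the path")
    1 / gv
  }
  vapply(phi, function(ph) {
    if (ph >= 0) gl_quad(invg, 0, ph, 48) else -gl_quad(invg, ph, 0, 48)
  }, numeric(1))
}

#' @rdname phi_transform
#' @export
tau_zeta <- function(zeta, cfg) {
  delta <- cfg$mat$x2 - cfg$mat$x1
  -t_transform(zeta, -delta, cfg)
}

#' Right-hand side of the transformed fixed-delay system
#'
#' The functional `G` of the fixed-delay system obtained by rescaling time
#' with the maturation speed: on histories over `[-delta, 0]`,
#' `G1 = q(psi(0)) phi(0) / g(psi(0))` and
#' `G2 = gamma(psi(-delta)) phi(-delta) / g(psi(-delta)) *
#'  exp(int_0^delta d(x2 - s, psi(-s)) / g(psi(-s)) ds) -
#'  mu psi(0) / g(psi(0))`.
#' Constant states are equilibria of `G` exactly when they are equilibria of
#' the original functional.
#'
#' @param state A [history_pair()] on `[-delta, 0]` (`h = delta`).
#' @param cfg A [model_config()] with maturity-independent `g`.
#' @param check Validate nonnegativity of the history (see [q_rate()]).
#' @return Numeric vector `c(G1, G2)`.
#' @export
transformed_rhs_G <- function(state, cfg, check = TRUE) {
  require_x_independent(cfg)
  stopifnot(inherits(state, "history_pair"))
  delta <- cfg$mat$x2 - cfg$mat$x1
  phi <- state$phi; psi <- state$psi
  psi0 <- psi(0); psid <- psi(-delta)
  stem <- cfg$stem
  ei <- if (cfg$d$zero) 0 else {
    gl_quad(function(s) {
      cfg$d$fun(cfg$mat$x2 - s, psi(-s)) / g_of_v(psi(-s), cfg, check = check)
    }, 0, delta, 64)
  }
  G1 <- q_rate(psi0, stem, check = check) * phi(0) / g_of_v(psi0, cfg, check = check)
  G2 <- gamma_rate(psid, stem, check = check) * phi(-delta) /
    g_of_v(psid, cfg, check = check) * exp(ei) -
    stem$mu * psi0 / g_of_v(psi0, cfg, check = check)
  c(G1, G2)
}

#' Transform a computed solution between the two time scales
#'
#' Forward: a solution `(w, v)` of the state-dependent system on `[0, T]` is
#' reparametrised by `phi = Phi_v(t)` (physiological time) to a solution
#' `(omega, u)` of the fixed-delay system.  Inverse: a solution
#' `(omega, u)` on `[0, Psi]` is pulled back by `t = T_u(phi)`.  In both
#' directions the map fixes constants and rescales time by the maturation
#' speed along the path.
#'
#' @param path A tibble/data.frame with columns `t`, `w`, `v` sampled densely
#'   (e.g. the `path` of [integrate_sdde()] or of [ps_integrate()]).
#' @param cfg A [model_config()] with maturity-independent `g`.
#' @param direction `"forward"` (original to physiological time) or
#'   `"inverse"`.
#' @return A tibble with columns `t` (the new independent variable), `w`,
#'   `v`.
#' @export
transform_solution <- function(path, cfg, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  require_x_independent(cfg)
  t_old <- path$t
  if (is.unsorted(t_old, strictly = TRUE)) stop("path times must be increasing")
  gv <- g_of_v(path$v, cfg)
  if (any(gv <= 0)) stop("maturation rate nonpositive along the path")
  integrand <- if (direction == "forward") gv else 1 / gv
  # cumulative integral of the (smooth, densely sampled) integrand
  spl <- stats::splinefun(t_old, integrand, method = "fmm")
  t_new <- c(0, cumsum(vapply(seq_len(length(t_old) - 1), function(i) {
    stats::integrate(spl, t_old[i], t_old[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))))
  tibble::tibble(t = t_new, w = path$w, v = path$v)
}

#' Eigenvalue correspondence between the two formulations
#'
#' At a positive equilibrium `(w, v)` the characteristic roots `z` of the
#' state-dependent system and the roots `lambda` of the transformed
#' fixed-delay system are in bijection via `lambda = z / g(v)`.  This
#' computes both spectra by pseudospectral discretisation, matches the
#' leading roots under the scaling, and reports the maximal mismatch; the
#' stability verdicts (sign of the rightmost real part) must agree.
#'
#' @param cfg A [model_config()] with maturity-independent `g`.
#' @param n_lead Number of leading (rightmost, physical) roots to match.
#' @param M Discretisation index.
#' @param filter_tol Physical-eigenvalue filter tolerance.
#' @return A list with `g_v`, a tibble `roots` (columns `z_re`, `z_im`,
#'   `mapped_re`, `mapped_im`, `mismatch`), `max_mismatch`, and
#'   `verdict_agrees`.
#' @export
eigenvalue_correspondence <- function(cfg, n_lead = 6, M = 15,
                                      filter_tol = 1e-3) {
  require_x_independent(cfg)
  eq <- positive_equilibrium(cfg)
  gv <- g_of_v(eq$v, cfg)
  sp_F <- ps_eigenvalues(cfg, eq, M = M, type = "sdde",
                         filter = TRUE, filter_tol = filter_tol)
  sp_G <- ps_eigenvalues(cfg, eq, M = M, type = "transformed",
                         filter = TRUE, filter_tol = filter_tol)
  zF <- complex(real = sp_F$re, imaginary = sp_F$im)[sp_F$physical]
  zG <- complex(real = sp_G$re, imaginary = sp_G$im)[sp_G$physical]
  n <- min(n_lead, length(zF))
  zF <- zF[seq_len(n)]
  mapped <- vapply(zF / gv, function(z) zG[which.min(abs(zG - z))], complex(1))
  mismatch <- abs(zF / gv - mapped)
  verdict <- sign(max(Re(zF))) == sign(max(Re(zG)))
  list(g_v = gv,
       roots = tibble::tibble(z_re = Re(zF), z_im = Im(zF),
                              mapped_re = Re(mapped), mapped_im = Im(mapped),
                              mismatch = mismatch),
       max_mismatch = max(mismatch),
       verdict_agrees = verdict)
}
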