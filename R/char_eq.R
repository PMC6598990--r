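# Characteristic functions for the trivial and positive equilibria, the
# simplified cascade for special rate choices, and root localisation in a
# rectangle by the argument principle.

#' Characteristic function of the trivial equilibrium
#'
#' The linearisation at `(0, 0)` is triangular, so the characteristic
#' function factorises as `(z - q(0)) (z + mu)`; its roots are `q(0)` and
#' `-mu`.
#'
#' @param z Complex (or real) frequency; vectorised.
#' @param cfg A [model_config()] (or [stem_params()]) object.
#' @return Complex vector.
#' @export
chi_trivial <- function(z, cfg) {
  stem <- if (inherits(cfg, "model_config")) cfg$stem else cfg
  (z - q_rate(0, stem)) * (z + stem$mu)
}

#' Characteristic context at the positive equilibrium
#'
#' Precomputes everything the characteristic function needs at a positive
#' equilibrium `v`: the threshold delay `tau(v)`, the constant-history
#' maturity trajectory `y(t, v)`, the derivative bundle, and the cumulative
#' integrals of `D1g` and of `D1(d - D1g)` along the trajectory that appear
#' in the kernel of the distributed-delay term.
#'
#' @param eq An `equilibrium` (positive kind) from [positive_equilibrium()],
#'   or `NULL` to compute it from `cfg`.
#' @param cfg A [model_config()] object.
#' @return An object of class `char_context`.
#' @export
char_context <- function(cfg, eq = NULL) {
  if (is.null(eq)) eq <- positive_equilibrium(cfg)
  stopifnot(inherits(eq, "equilibrium"), eq$kind == "positive")
  v <- eq$v; tau <- eq$tau_eq
  dv <- rate_derivatives(cfg)
  mat <- cfg$mat
  kernel_zero <- cfg$d$zero && g_is_x_independent(mat)
  if (kernel_zero) {
    yfun <- traj_constant_v(v, tau, cfg)
    Qfun <- function(t) rep(0, length(t))
    Rfun <- Qfun
  } else {
    # joint dense solve of y' = -g(y, v), Q' = D1g(y, v),
    # R' = D1(d - D1g)(y, v) e^{-Q}
    deriv <- function(s, y, parms) {
      yy <- y[1]
      list(c(-g_rate(yy, v, mat, x_tol = 0.05),
             dv$D1g(yy, v),
             (dv$D1d(yy, v) - dv$D1D1g(yy, v)) * exp(-y[2])))
    }
    times <- seq(0, tau, length.out = 241)
    sol <- deSolve::lsoda(y = c(mat$x2, 0, 0), times = times, func = deriv,
                          parms = NULL, rtol = 1e-12, atol = 1e-12)
    ys <- stats::splinefun(sol[, 1], sol[, 2], method = "fmm")
    Qs <- stats::splinefun(sol[, 1], sol[, 3], method = "fmm")
    Rs <- stats::splinefun(sol[, 1], sol[, 4], method = "fmm")
    yfun <- function(t) pmin(pmax(ys(t), mat$x1), mat$x2)
    Qfun <- Qs; Rfun <- Rs
  }
  structure(list(eq = eq, cfg = cfg, v = v, tau = tau, deriv = dv,
                 y = yfun, Q = Qfun, R = Rfun, kernel_zero = kernel_zero),
            class = "char_context")
}

#' Kernel of the distributed-delay term
#'
#' Evaluates the kernel `k(v)(t)` of the characteristic function on
#' `[0, tau(v)]`.  It collects the sensitivities of the maturation flow to
#' the mature-cell amount: the direct `D2(d - D1g)` term, a boundary term
#' proportional to `(d - D1g)/g` at `x1` damped by the accumulated dilation,
#' and the integrated interaction of `D2g` with `D1(d - D1g)` along the
#' trajectory.  It vanishes identically when `d` is zero and `g` does not
#' depend on maturity.
#'
#' @param t Time(s) in `[0, tau(v)]`; vectorised.
#' @param ctx A [char_context()].
#' @return Numeric vector.
#' @export
kernel_k <- function(t, ctx) {
  if (any(t < -1e-12) || any(t > ctx$tau * (1 + 1e-9) + 1e-12)) {
    stop("kernel argument outside [0, tau]")
  }
  if (ctx$kernel_zero) return(rep(0, length(t)))
  cfg <- ctx$cfg; dv <- ctx$deriv; v <- ctx$v; mat <- cfg$mat
  mu <- cfg$stem$mu
  yt <- ctx$y(t)
  Qt <- ctx$Q(t); Qtau <- ctx$Q(ctx$tau)
  Rt <- ctx$R(t); Rtau <- ctx$R(ctx$tau)
  term1 <- dv$D2d(yt, v) - dv$D2D1g(yt, v)
  dmD1g_x1 <- (cfg$d$fun(mat$x1, v) - dv$D1g(mat$x1, v)) / g_rate(mat$x1, v, mat)
  term2 <- dmD1g_x1 * exp(-(Qtau - Qt)) * dv$D2g(yt, v)
  term3 <- dv$D2g(yt, v) * exp(Qt) * (Rtau - Rt)
  mu * v * (term1 - term2 - term3)
}

# Laplace transform of the kernel on [0, tau], Gauss-Legendre with the order
# grown until the value is stable to 1e-10 relative
kernel_hat <- function(z, ctx) {
  if (ctx$kernel_zero) return(rep(0 + 0i, length(z)))
  val_for <- function(n) {
    gl <- pracma::gaussLegendre(n, 0, ctx$tau)
    kv <- kernel_k(gl$x, ctx)
    vapply(z, function(zz) sum(gl$w * kv * exp(-zz * gl$x)), complex(1))
  }
  prev <- val_for(32)
  for (n in c(64, 128, 256)) {
    cur <- val_for(n)
    if (max(abs(cur - prev)) <= 1e-10 * max(1, max(abs(cur)))) return(cur)
    prev <- cur
  }
  prev
}

#' Characteristic function of the positive equilibrium
#'
#' Evaluates `chi(v, z) = z k_hat(z) + mu v e^{-tau z} [z (gamma'/gamma(v) -
#' D2g/g(x1, v)) + q'(v)] - z^2 + (v D2g/g(x2, v) - 1) mu z`, where `k_hat`
#' is the finite Laplace transform of the kernel on `[0, tau(v)]`.  The
#' equilibrium is locally asymptotically stable when all roots have negative
#' real part.
#'
#' @param z Complex frequency; vectorised.
#' @param ctx A [char_context()].
#' @return Complex vector.
#' @export
chi <- function(z, ctx) {
  z <- as.complex(z)
  cfg <- ctx$cfg; dv <- ctx$deriv; v <- ctx$v; tau <- ctx$tau
  mat <- cfg$mat; mu <- cfg$stem$mu
  gg1 <- dv$D2g(mat$x1, v) / g_rate(mat$x1, v, mat)
  gg2 <- dv$D2g(mat$x2, v) / g_rate(mat$x2, v, mat)
  gam_ratio <- dv$gammap(v) / gamma_rate(v, cfg$stem)
  z * kernel_hat(z, ctx) +
    mu * v * exp(-tau * z) * (z * (gam_ratio - gg1) + dv$qp(v)) -
    z^2 + (v * gg2 - 1) * mu * z
}

#' Simplified characteristic functions
#'
#' The cascade of closed forms obtained under successively stronger
#' assumptions, each evaluated exactly as stated:
#' \describe{
#'   \item{`"a"`}{`g` independent of maturity: distributed kernel reduces to
#'     `mu v (D2d - g'/g d)` along the trajectory.}
#'   \item{`"b"`}{additionally `D2d = 0`, `D2g = 0` (constant `g`):
#'     `mu v [gamma'/gamma z + q'(v)] e^{-tau z} - z^2 - mu z`.}
#'   \item{`"c"`}{rates from the regulated stem-cell family:
#'     coefficients expressed through `d_w` and `s`.}
#'   \item{`"d"`}{unregulated self-renewal (`k_a = 0`):
#'     `(d_w'/d_w)(v) mu v (z + mu_w) e^{-tau z} - z^2 - mu z`.}
#'   \item{`"e"`}{division rate of the regulated family:
#'     `[1 - mu_w/((2a-1)p)] mu (z + mu_w) e^{-z tau} + z^2 + mu z` (overall
#'     sign flipped relative to case `"d"`; the root set is unchanged).}
#' }
#'
#' @param z Complex frequency; vectorised.
#' @param cfg A [model_config()] object satisfying the case hypotheses.
#' @param case One of `"a"`, `"b"`, `"c"`, `"d"`, `"e"`.
#' @param v Equilibrium mature-cell amount; computed from `cfg` when `NULL`
#'   (cases `"a"`-`"d"`; case `"e"` does not need it).
#' @param tau Delay; computed from `cfg` (at `v` for case `"a"`, fixed
#'   `(x2 - x1)/g` otherwise) when `NULL`.
#' @return Complex vector.
#' @export
chi_simplified <- function(z, cfg, case = c("e", "a", "b", "c", "d"),
                           v = NULL, tau = NULL) {
  case <- match.arg(case)
  z <- as.complex(z)
  stem <- cfg$stem; mat <- cfg$mat; mu <- stem$mu
  if (!g_is_x_independent(mat)) {
    stop("case hypotheses require a maturation rate independent of maturity")
  }
  if (case %in% c("b", "c", "d", "e")) {
    if (!g_is_constant(mat)) stop("cases b-e require a constant maturation rate")
    if (!cfg$d$zero) stop("cases b-e require zero progenitor net production")
  }
  if (case %in% c("d", "e") && stem$k_a != 0) {
    stop("cases d and e require unregulated self-renewal (k_a = 0)")
  }
  if (is.null(v) && case != "e") v <- positive_equilibrium(cfg)$v
  if (is.null(tau)) {
    tau <- if (case == "a") tau_constant_history(v, cfg)
           else (mat$x2 - mat$x1) / g_rate(mat$x1, 0, mat)
  }
  dv <- rate_derivatives(cfg)
  switch(case,
    a = {
      ctx <- char_context(cfg, eq = new_equilibrium(NA_real_, v, "positive",
                                                    NA_real_, tau))
      chi(z, ctx)
    },
    b = {
      gam_ratio <- dv$gammap(v) / gamma_rate(v, stem)
      mu * v * (gam_ratio * z + dv$qp(v)) * exp(-tau * z) - z^2 - mu * z
    },
    c = {
      s <- s_frac(v, stem); dw <- dw_rate(v, stem)
      sp <- -stem$a * stem$k_a / (1 + stem$k_a * v)^2
      dwp <- -stem$p * stem$k_p / (1 + stem$k_p * v)^2
      mu * v * ((dwp / dw - sp / (1 - s)) * z +
                  2 * sp * dw + dwp * (2 * s - 1)) * exp(-tau * z) -
        z^2 - mu * z
    },
    d = {
      dw <- dw_rate(v, stem)
      dwp <- -stem$p * stem$k_p / (1 + stem$k_p * v)^2
      (dwp / dw) * mu * v * (z + stem$mu_w) * exp(-tau * z) - z^2 - mu * z
    },
    e = {
      (1 - stem$mu_w / ((2 * stem$a - 1) * stem$p)) * mu * (z + stem$mu_w) *
        exp(-z * tau) + z^2 + mu * z
    })
}


## ---- root localisation by the argument principle ---------------------------

# winding number of f along the rectangle boundary, by adaptive phase tracking
winding_number <- function(f, rect, n0 = 64, max_refine = 14) {
  corners <- c(complex(real = rect$re[1], imaginary = rect$im[1]),
               complex(real = rect$re[2], imaginary = rect$im[1]),
               complex(real = rect$re[2], imaginary = rect$im[2]),
               complex(real = rect$re[1], imaginary = rect$im[2]),
               complex(real = rect$re[1], imaginary = rect$im[1]))
  pts <- unlist(lapply(1:4, function(i) {
    s <- seq(0, 1, length.out = n0 + 1)[-(n0 + 1)]
    corners[i] + s * (corners[i + 1] - corners[i])
  }))
  pts <- c(pts, corners[1])
  vals <- f(pts)
  if (any(abs(vals) == 0)) stop("root on the scan-rectangle boundary; perturb")
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + phase_step(f, pts[i], pts[i + 1], vals[i], vals[i + 1],
                                depth = max_refine)
  }
  round(total / (2 * pi))
}

phase_step <- function(f, z1, z2, f1, f2, depth) {
  d <- Arg(f2 / f1)
  if (abs(d) < pi / 2) return(d)
  if (depth <= 0) {
    stop("winding inconsistency: phase cannot be tracked on the boundary ",
         "(root too close to the scan rectangle?)")
  }
  zm <- (z1 + z2) / 2
  fm <- f(zm)
  if (abs(fm) == 0) stop("root on the scan-rectangle boundary; perturb")
  phase_step(f, z1, zm, f1, fm, depth - 1) +
    phase_step(f, zm, z2, fm, f2, depth - 1)
}

newton_polish <- function(f, z0, tol = 1e-13, maxit = 60) {
  z <- z0
  for (i in seq_len(maxit)) {
    hstep <- 1e-7 * (1 + abs(z))
    df <- (f(z + hstep) - f(z - hstep)) / (2 * hstep)
    if (abs(df) == 0) return(NULL)
    dz <- f(z) / df
    z <- z - dz
    if (!is.finite(Re(z)) || !is.finite(Im(z))) return(NULL)
    if (abs(dz) <= tol * (1 + abs(z))) return(z)
  }
  NULL
}

#' Locate characteristic roots in a rectangle
#'
#' Counts roots by the argument principle (winding number of the
#' characteristic function along the rectangle boundary), subdivides until
#' each sub-rectangle contains a single root, polishes each by Newton
#' iteration and certifies it by its residual.  The total number of returned
#' roots always equals the winding number of the initial rectangle.
#'
#' @param f A function of a complex vector, e.g. `function(z) chi(z, ctx)`.
#' @param re Real-part range `c(lo, hi)` of the scan rectangle.
#' @param im_max Half-height: the rectangle spans `|Im z| <= im_max`.
#' @param min_size Sub-rectangles smaller than this are treated as a single
#'   (possibly multiple) root location.
#' @return Tibble with columns `re`, `im`, `residual`, `multiple`.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0,(px)_1")
#' find_roots(function(z) chi_trivial(z, cfg), re = c(-2, 1), im_max = 1)
#' @export
find_roots <- function(f, re, im_max, min_size = 1e-9) {
  rect0 <- list(re = sort(re), im = c(-im_max, im_max))
  roots <- list()
  stack <- list(rect0)
  nwind0 <- winding_number(f, rect0)
  while (length(stack) > 0) {
    rect <- stack[[1]]; stack <- stack[-1]
    n <- winding_number(f, rect)
    if (n == 0) next
    w <- rect$re[2] - rect$re[1]; hgt <- rect$im[2] - rect$im[1]
    centre <- complex(real = mean(rect$re), imaginary = mean(rect$im))
    if (n == 1) {
      z <- newton_polish(f, centre)
      inside <- !is.null(z) &&
        Re(z) >= rect$re[1] - 1e-10 && Re(z) <= rect$re[2] + 1e-10 &&
        Im(z) >= rect$im[1] - 1e-10 && Im(z) <= rect$im[2] + 1e-10
      if (inside) {
        roots[[length(roots) + 1]] <-
          list(z = z, residual = abs(f(z)), multiple = FALSE)
        next
      }
    }
    if (max(w, hgt) < min_size) {
      roots[[length(roots) + 1]] <-
        list(z = centre, residual = abs(f(centre)), multiple = n > 1)
      next
    }
    off <- 0.5 + 1e-3  # asymmetric cut so roots rarely land on it
    if (w >= hgt) {
      cut <- rect$re[1] + off * w
      stack <- c(stack, list(list(re = c(rect$re[1], cut), im = rect$im),
                             list(re = c(cut, rect$re[2]), im = rect$im)))
    } else {
      cut <- rect$im[1] + off * hgt
      stack <- c(stack, list(list(re = rect$re, im = c(rect$im[1], cut)),
                             list(re = rect$re, im = c(cut, rect$im[2]))))
    }
  }
  if (length(roots) != nwind0) {
    warning("root count (", length(roots),
            ") differs from the boundary winding number (", nwind0, ")")
  }
  zs <- vapply(roots, function(r) r$z, complex(1))
  ord <- order(-Re(zs), abs(Im(zs)))
  tibble::tibble(
    re = Re(zs)[ord], im = Im(zs)[ord],
    residual = vapply(roots, function(r) r$residual, numeric(1))[ord],
    multiple = vapply(roots, function(r) r$multiple, logical(1))[ord])
}

#' Roots of the characteristic equation for a configured equilibrium
#'
#' Convenience wrapper around [find_roots()] using the default scan
#' rectangle `Re z` in `[-5 s, 5 s]` with `s = max(mu, mu_w, p)` and
#' `|Im z| <= 20 pi / tau`.
#'
#' @param cfg A [model_config()] object.
#' @param equilibrium `"positive"` or `"trivial"`.
#' @param re,im_max Optional overrides of the scan rectangle.
#' @return Tibble as in [find_roots()], ordered by decreasing real part.
#' @export
char_roots <- function(cfg, equilibrium = c("positive", "trivial"),
                       re = NULL, im_max = NULL) {
  equilibrium <- match.arg(equilibrium)
  s <- max(cfg$stem$mu, cfg$stem$mu_w, cfg$stem$p)
  if (equilibrium == "trivial") {
    f <- function(z) chi_trivial(z, cfg)
    if (is.null(re)) re <- c(-2 * cfg$stem$mu - 1, 2 * abs(q_rate(0, cfg$stem)) + 1)
    if (is.null(im_max)) im_max <- 1
  } else {
    ctx <- char_context(cfg)
    f <- function(z) chi(z, ctx)
    if (is.null(re)) re <- c(-5 * s, 5 * s)
    if (is.null(im_max)) im_max <- 20 * pi / ctx$tau
  }
  find_roots(f, re = re, im_max = im_max)
}
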