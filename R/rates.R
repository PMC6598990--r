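# Model ingredients: stem-cell rates, maturation rate, progenitor production,
# named parameter scenarios and closed-form partial derivatives.

#' Stem-cell rate parameters
#'
#' Bundles the parameters of the regulated stem-cell rates: the division rate
#' `d_w(v) = p / (1 + k_p v)`, the fraction of self-renewal
#' `s(v) = a / (1 + k_a v)`, the stem-cell mortality `mu_w` and the
#' mature-cell mortality `mu`.  The net growth rate of the stem-cell
#' population is `q(v) = [2 s(v) - 1] d_w(v) - mu_w` and the rate of inflow
#' into the progenitor compartment is `gamma(v) = 2 [1 - s(v)] d_w(v)`.
#'
#' @param mu Mature-cell per-capita death rate (1/time, > 0).
#' @param mu_w Stem-cell mortality rate (1/time, >= 0).
#' @param a Maximal fraction of self-renewal (dimensionless, must exceed 0.5).
#' @param p Maximal division rate (1/time, >= 0).
#' @param k_a Feedback strength of mature cells on self-renewal (per cell, >= 0).
#' @param k_p Feedback strength of mature cells on division (per cell, >= 0).
#'
#' @return An object of class `stem_params`.
#' @examples
#' sp <- stem_params(mu = 1, mu_w = 1, a = 0.9, p = 2, k_a = 0, k_p = 1)
#' q_rate(0, sp)      # (2*0.9 - 1)*2 - 1 = 0.6
#' @export
stem_params <- function(mu = 1, mu_w = 1, a = 0.9, p = 2, k_a = 0, k_p = 0) {
  vals <- c(mu = mu, mu_w = mu_w, a = a, p = p, k_a = k_a, k_p = k_p)
  if (any(!is.finite(vals))) stop("all stem-cell parameters must be finite")
  if (mu <= 0) stop("mature-cell mortality 'mu' must be positive")
  if (a <= 0.5) stop("maximal self-renewal fraction 'a' must exceed 0.5")
  if (any(c(mu_w, p, k_a, k_p) < 0)) stop("rates must be nonnegative")
  structure(as.list(vals), class = "stem_params")
}

#' @export
print.stem_params <- function(x, ...) {
  cat("Stem-cell rates: mu =", x$mu, " mu_w =", x$mu_w, " a =", x$a,
      " p =", x$p, " k_a =", x$k_a, " k_p =", x$k_p, "\n")
  invisible(x)
}

check_v <- function(v) {
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("mature-cell amount 'v' must be finite and nonnegative")
  }
  invisible(v)
}

#' Stem-cell rate functions
#'
#' `s_frac()` and `dw_rate()` evaluate the fraction of self-renewal and the
#' division rate; `q_rate()` the net growth rate of the stem-cell population;
#' `gamma_rate()` the rate of inflow into the progenitor compartment.  All are
#' vectorised in `v`.
#'
#' @param v Mature-cell amount (>= 0); may be a vector.
#' @param stem A [stem_params()] object.
#' @param check Validate the domain of `v`; internal linearisation code may
#'   disable this to evaluate the (rational) rate formulas in a small
#'   neighbourhood of an admissible state.
#' @return Numeric vector of rates.
#' @export
q_rate <- function(v, stem, check = TRUE) {
  if (check) check_v(v)
  (2 * s_frac(v, stem) - 1) * dw_rate(v, stem) - stem$mu_w
}

#' @rdname q_rate
#' @export
gamma_rate <- function(v, stem, check = TRUE) {
  if (check) check_v(v)
  2 * (1 - s_frac(v, stem)) * dw_rate(v, stem)
}

#' @rdname q_rate
#' @export
s_frac <- function(v, stem) stem$a / (1 + stem$k_a * v)

#' @rdname q_rate
#' @export
dw_rate <- function(v, stem) stem$p / (1 + stem$k_p * v)


## ---- maturity profiles -----------------------------------------------------

#' Maturity-dependent coefficient profiles
#'
#' The maturation rate carries two maturity-dependent coefficients, a
#' division-like coefficient `p_u(x)` and a self-renewal-like coefficient
#' `a_u(x)`.  A profile is represented either by polynomial coefficients
#' (constant, linear or quadratic; ascending order) with exact derivatives,
#' or by an arbitrary function of `x`, in which case derivatives are taken
#' by central finite differences.
#'
#' @param spec A single number (constant profile), a numeric vector of
#'   polynomial coefficients in ascending order, or a function of `x`.
#' @return An object of class `maturity_profile` with elements `fun`, `dfun`
#'   and `d2fun`, each a vectorised function of `x`.
#' @examples
#' pr <- maturity_profile(c(0.1 + 2.8 * 0.25, -2.8, 2.8))  # 0.1 + 2.8 (x-1/2)^2
#' pr$fun(0.5)
#' @export
maturity_profile <- function(spec) {
  if (inherits(spec, "maturity_profile")) return(spec)
  if (is.numeric(spec)) {
    coef <- as.numeric(spec)
    structure(list(
      fun   = poly_fun(coef),
      dfun  = poly_fun(poly_deriv(coef)),
      d2fun = poly_fun(poly_deriv(poly_deriv(coef))),
      kind  = "poly", coef = coef
    ), class = "maturity_profile")
  } else if (is.function(spec)) {
    structure(list(
      fun   = spec,
      dfun  = fd_deriv(spec),
      d2fun = fd_deriv(fd_deriv(spec)),
      kind  = "function"
    ), class = "maturity_profile")
  } else {
    stop("profile must be numeric coefficients or a function")
  }
}

poly_fun <- function(coef) {
  force(coef)
  function(x) {
    out <- rep(0, length(x))
    for (j in rev(seq_along(coef))) out <- out * x + coef[j]
    out
  }
}

poly_deriv <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

# central finite difference with relative step; used for user-supplied profiles
fd_deriv <- function(f, rel_step = 1e-6) {
  force(f); force(rel_step)
  function(x) {
    h <- rel_step * pmax(1, abs(x))
    (f(x + h) - f(x - h)) / (2 * h)
  }
}

is_constant_profile <- function(pr) pr$kind == "poly" && length(pr$coef) == 1


## ---- maturation parameters -------------------------------------------------

#' Maturation-rate parameters
#'
#' Parameters of the progenitor maturation rate
#' `g(x, v) = g0 + 2 p_u(x) / (1 + k1 v) * (1 - a_u(x) / (1 + k2 v))`,
#' defined on the maturity interval `[x1, x2]`.  Feedback by the mature-cell
#' amount `v` can decrease (`k1`) or increase (`k2`) the maturation speed.
#' Positivity of `g` is required for the threshold delay to be defined; it is
#' checked at construction on a 101 x 101 grid over `[x1, x2] x [0, v_max]`.
#'
#' @param x1,x2 Maturity interval endpoints, `x1 < x2`.
#' @param g0 Baseline maturation speed (>= 0).
#' @param k1 Feedback strength decreasing `g` in `v` (>= 0).
#' @param k2 Feedback strength increasing `g` in `v` (>= 0).
#' @param a_u,p_u Maturity profiles, anything accepted by [maturity_profile()].
#' @param v_max Upper end of the `v` range used for the positivity check.
#' @return An object of class `maturation_params`.
#' @export
maturation_params <- function(x1 = 0, x2 = 1, g0 = 0, k1 = 0, k2 = 0,
                              a_u = 1 / 3, p_u = 0.3, v_max = 100) {
  if (!(x2 > x1)) stop("maturity interval must satisfy x1 < x2")
  if (g0 < 0 || k1 < 0 || k2 < 0) stop("g0, k1, k2 must be nonnegative")
  mat <- structure(list(
    x1 = x1, x2 = x2, g0 = g0, k1 = k1, k2 = k2,
    a_u = maturity_profile(a_u), p_u = maturity_profile(p_u),
    v_max = v_max
  ), class = "maturation_params")
  xg <- seq(x1, x2, length.out = 101)
  vg <- seq(0, v_max, length.out = 101)
  gmin <- min(outer(xg, vg, function(x, v) g_rate(x, v, mat)))
  if (gmin <= 0) {
    stop(sprintf("maturation rate g is not positive on [x1,x2] x [0,%g] (min %.3g)",
                 v_max, gmin))
  }
  mat
}

#' @export
print.maturation_params <- function(x, ...) {
  cat("Maturation rate on [", x$x1, ",", x$x2, "]: g0 =", x$g0,
      " k1 =", x$k1, " k2 =", x$k2,
      " (a_u:", x$a_u$kind, ", p_u:", x$p_u$kind, ")\n")
  invisible(x)
}

#' Maturation rate
#'
#' Evaluates `g(x, v) = g0 + 2 p_u(x)/(1 + k1 v) * (1 - a_u(x)/(1 + k2 v))`.
#' A small extrapolation tolerance outside `[x1, x2]` is allowed so that
#' adaptive solvers may overshoot the maturity interval.
#'
#' @param x Maturity; vectorised.
#' @param v Mature-cell amount (>= 0); scalar or vector conformable with `x`.
#' @param mat A [maturation_params()] object.
#' @param x_tol Allowed relative overshoot beyond the maturity interval.
#' @param check Validate the domain of `v` (see [q_rate()]).
#' @return Maturation speed(s), strictly positive.
#' @export
g_rate <- function(x, v, mat, x_tol = 1e-6, check = TRUE) {
  if (check) check_v(v)
  span <- mat$x2 - mat$x1
  if (any(x < mat$x1 - x_tol * span - x_tol) ||
      any(x > mat$x2 + x_tol * span + x_tol)) {
    stop("maturity 'x' outside the maturity interval")
  }
  mat$g0 + 2 * mat$p_u$fun(x) / (1 + mat$k1 * v) *
    (1 - mat$a_u$fun(x) / (1 + mat$k2 * v))
}


## ---- model configuration ---------------------------------------------------

#' Full model configuration
#'
#' Combines the stem-cell rates, the maturation rate and the progenitor net
#' production rate `d(x, v)` into one model instance.  By default `d` is
#' identically zero (progenitor death and self-renewal in balance).  The
#' history horizon `h` must strictly exceed the threshold delay at every
#' state encountered; by default it is set to twice the largest threshold
#' delay over `v` in `[0, v_max]`.
#'
#' @param stem A [stem_params()] object.
#' @param mat A [maturation_params()] object.
#' @param d Optional progenitor net production: either `NULL` (zero), or a
#'   list with vectorised functions `fun(x, v)`, and optionally `D1`, `D2`
#'   (partial derivatives; finite differences are used if missing).
#' @param h Optional history horizon; computed from the delay range if `NULL`.
#' @return An object of class `model_config`.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0")
#' cfg$h
#' @export
model_config <- function(stem, mat, d = NULL, h = NULL) {
  stopifnot(inherits(stem, "stem_params"), inherits(mat, "maturation_params"))
  if (!is.null(d)) {
    stopifnot(is.list(d), is.function(d$fun))
    if (is.null(d$D1)) d$D1 <- function(x, v) fd_deriv(function(xx) d$fun(xx, v))(x)
    if (is.null(d$D2)) d$D2 <- function(x, v) fd_deriv(function(vv) d$fun(x, vv))(v)
    d$zero <- FALSE
  } else {
    zf <- function(x, v) rep(0, max(length(x), length(v)))
    d <- list(fun = zf, D1 = zf, D2 = zf, zero = TRUE)
  }
  cfg <- structure(list(stem = stem, mat = mat, d = d, h = h),
                   class = "model_config")
  if (is.null(h)) {
    vg <- seq(0, mat$v_max, length.out = 17)
    taus <- vapply(vg, function(v) tau_constant_history(v, cfg), numeric(1))
    cfg$h <- 2 * max(taus)
  } else if (h <= 0) {
    stop("history horizon 'h' must be positive")
  }
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  print(x$stem); print(x$mat)
  cat("Progenitor net production d:", if (x$d$zero) "zero" else "custom",
      "  horizon h =", format(x$h), "\n")
  invisible(x)
}

#' Progenitor net production rate
#'
#' @param x Maturity.
#' @param v Mature-cell amount (>= 0).
#' @param cfg A [model_config()] object.
#' @return `d(x, v)`; identically zero for the default configuration.
#' @export
d_rate <- function(x, v, cfg) {
  check_v(v)
  cfg$d$fun(x, v)
}

# TRUE when g does not depend on x (constant profiles), so the fixed-delay
# time transformation applies
g_is_x_independent <- function(mat) {
  is_constant_profile(mat$a_u) && is_constant_profile(mat$p_u)
}

# TRUE when g is a single constant (no x and no v dependence)
g_is_constant <- function(mat) {
  g_is_x_independent(mat) && mat$k1 == 0 && mat$k2 == 0
}


## ---- derivatives -----------------------------------------------------------

#' Closed-form partial derivatives of the model rates
#'
#' Returns the derivative bundle needed by the characteristic equation:
#' `qp(v)` and `gammap(v)` (derivatives of the stem-cell net growth and
#' inflow rates), and the partials `D1g`, `D2g`, `D1D1g`, `D2D1g` of the
#' maturation rate together with `D1d`, `D2d` of the production rate.
#' Polynomial profiles yield exact expressions; user-supplied functions fall
#' back to central finite differences (relative step `1e-6`).
#'
#' @param cfg A [model_config()] object.
#' @return A list of vectorised functions, class `rate_derivatives`.
#' @export
rate_derivatives <- function(cfg) {
  st <- cfg$stem; mat <- cfg$mat
  a <- st$a; p <- st$p; ka <- st$k_a; kp <- st$k_p
  k1 <- mat$k1; k2 <- mat$k2
  P  <- mat$p_u$fun;  Pp  <- mat$p_u$dfun;  Ppp  <- mat$p_u$d2fun
  A  <- mat$a_u$fun;  Ap  <- mat$a_u$dfun;  App  <- mat$a_u$d2fun
  # products (PA)' and (PA)''
  PAp  <- function(x) Pp(x) * A(x) + P(x) * Ap(x)
  PApp <- function(x) Ppp(x) * A(x) + 2 * Pp(x) * Ap(x) + P(x) * App(x)
  # d/dv of 1/((1+k1 v)(1+k2 v)) = -S(v)/denominator^2 with
  S12 <- function(v) k1 * (1 + k2 * v) + k2 * (1 + k1 * v)
  den12 <- function(v) (1 + k1 * v) * (1 + k2 * v)

  bundle <- list(
    qp = function(v) {
      # q(v) = 2 a p / ((1+ka v)(1+kp v)) - p/(1+kp v) - mu_w
      -2 * a * p * (ka * (1 + kp * v) + kp * (1 + ka * v)) /
        ((1 + ka * v)^2 * (1 + kp * v)^2) + p * kp / (1 + kp * v)^2
    },
    gammap = function(v) {
      # gamma(v) = 2 p/(1+kp v) - 2 a p/((1+ka v)(1+kp v))
      -2 * p * kp / (1 + kp * v)^2 +
        2 * a * p * (ka * (1 + kp * v) + kp * (1 + ka * v)) /
          ((1 + ka * v)^2 * (1 + kp * v)^2)
    },
    D1g = function(x, v) {
      2 * Pp(x) / (1 + k1 * v) - 2 * PAp(x) / den12(v)
    },
    D2g = function(x, v) {
      -2 * P(x) * k1 / (1 + k1 * v)^2 + 2 * P(x) * A(x) * S12(v) / den12(v)^2
    },
    D1D1g = function(x, v) {
      2 * Ppp(x) / (1 + k1 * v) - 2 * PApp(x) / den12(v)
    },
    D2D1g = function(x, v) {
      -2 * Pp(x) * k1 / (1 + k1 * v)^2 + 2 * PAp(x) * S12(v) / den12(v)^2
    },
    D1d = cfg$d$D1,
    D2d = cfg$d$D2
  )
  structure(bundle, class = "rate_derivatives")
}


## ---- named scenarios -------------------------------------------------------

#' Named parameter scenarios
#'
#' Builds a [model_config()] from the scenario labels used in the numerical
#' study.  The fixed baseline is `x1 = 0`, `x2 = 1`, `mu_w = 1`, `a = 0.9`.
#' Components (comma separated, in any order):
#' \describe{
#'   \item{`(s)_s`}{regulated self-renewal, unregulated division:
#'     `k_a = 1, k_p = 0`.}
#'   \item{`(s)_d`}{unregulated self-renewal, regulated division:
#'     `k_a = 0, k_p = 1` (default).}
#'   \item{`(pv)_0`, `(pv)_1`, `(pv)_2`}{maturation independent of `v`
#'     (`k1 = k2 = 0`, default), decreasing in `v` (`k1 = 1`), or increasing
#'     in `v` (`k2 = 1`).}
#'   \item{`(px)_1`}{`p_u(x) = 0.3` with `a_u` constant `1/3`, linear
#'     `2/3 (1 - x)` or quadratic `0.1 + 2.8 (x - 0.5)^2`.}
#'   \item{`(px)_2`}{`p_u(x) = p` with `a_u` constant `0.9`, linear
#'     `0.99 - 0.18 x` or quadratic `0.855 - 0.54 (x - 0.5)^2`.}
#'   \item{`constant` / `linear` / `quadratic`}{selects the `a_u` profile for
#'     a `(px)` component (default `constant`).}
#' }
#' Without a `(px)` component the maturity profiles are the constants
#' `a_u = a` and `p_u = p` (with `p` the stem-cell division parameter), as in
#' the `v`-regulated maturation cases of the numerical study.
#'
#' @param label Scenario string, e.g. `"(s)_d,(pv)_0"` or
#'   `"(s)_s,(pv)_2,(px)_1,quadratic"`.
#' @param p Maximal stem-cell division rate.
#' @param mu Mature-cell mortality.
#' @param g0 Baseline maturation speed.
#' @param k_a,k_p Optional overrides for the stem-cell feedback strengths
#'   (e.g. simultaneous regulation `k_a = k_p = 1`).
#' @param v_max Range bound used for positivity checks and the default horizon.
#' @param h Optional history horizon override.
#' @return A [model_config()].
#' @examples
#' scenario("(s)_d,(pv)_0", p = 2, mu = 1, g0 = 0.4)
#' @export
scenario <- function(label, p = 2, mu = 1, g0 = 0,
                     k_a = NULL, k_p = NULL, v_max = 100, h = NULL) {
  parts <- trimws(strsplit(label, ",")[[1]])
  parts <- parts[nzchar(parts)]
  known <- c("(s)_s", "(s)_d", "(pv)_0", "(pv)_1", "(pv)_2",
             "(px)_1", "(px)_2", "constant", "linear", "quadratic")
  bad <- setdiff(parts, known)
  if (length(bad)) {
    stop("unknown scenario component(s): ", paste(bad, collapse = ", "))
  }
  pick <- function(opts, default) {
    sel <- intersect(parts, opts)
    if (length(sel) > 1) stop("conflicting scenario components: ",
                              paste(sel, collapse = ", "))
    if (length(sel) == 0) default else sel
  }
  s_comp  <- pick(c("(s)_s", "(s)_d"), "(s)_d")
  pv_comp <- pick(c("(pv)_0", "(pv)_1", "(pv)_2"), "(pv)_0")
  px_comp <- pick(c("(px)_1", "(px)_2"), NA_character_)
  shape   <- pick(c("constant", "linear", "quadratic"), "constant")

  a <- 0.9; mu_w <- 1
  if (is.null(k_a)) k_a <- if (s_comp == "(s)_s") 1 else 0
  if (is.null(k_p)) k_p <- if (s_comp == "(s)_s") 0 else 1
  k1 <- if (pv_comp == "(pv)_1") 1 else 0
  k2 <- if (pv_comp == "(pv)_2") 1 else 0

  if (is.na(px_comp)) {
    p_u <- p; a_u <- a
  } else if (px_comp == "(px)_1") {
    p_u <- 0.3
    a_u <- switch(shape,
      constant  = 1 / 3,
      linear    = c(2 / 3, -2 / 3),
      quadratic = c(0.1 + 2.8 * 0.25, -2.8, 2.8))
  } else {
    p_u <- p
    a_u <- switch(shape,
      constant  = 0.9,
      linear    = c(0.99, -0.18),
      quadratic = c(0.855 - 0.54 * 0.25, 0.54, -0.54))
  }

  stem <- stem_params(mu = mu, mu_w = mu_w, a = a, p = p, k_a = k_a, k_p = k_p)
  mat <- maturation_params(x1 = 0, x2 = 1, g0 = g0, k1 = k1, k2 = k2,
                           a_u = a_u, p_u = p_u, v_max = v_max)
  model_config(stem, mat, h = h)
}
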