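# The state-dependent delay equation itself: maturity trajectory, threshold
# delay, right-hand-side functional F = (F1, F2), and time integration by the
# method of steps.

#' History pair
#'
#' The state of the delay system: a pair of functions on `[-h, 0]`, the
#' stem-cell history `phi` and the mature-cell history `psi`.  Constants are
#' promoted to constant functions.  Negative mature-cell histories are
#' rejected: the model rates are defined for nonnegative `v` only.
#'
#' @param phi Stem-cell history: a constant or a function on `[-h, 0]`.
#' @param psi Mature-cell history: a constant (>= 0) or a function on
#'   `[-h, 0]` with nonnegative values.
#' @param h History horizon (> 0).
#' @return An object of class `history_pair`.
#' @examples
#' hp <- history_pair(2.4, 0.6, h = 5)
#' hp$psi(-1)
#' @export
history_pair <- function(phi, psi, h) {
  stopifnot(is.finite(h), h > 0)
  as_hist <- function(f, name) {
    if (is.numeric(f) && length(f) == 1) {
      val <- f
      out <- function(theta) rep(val, length(theta))
      attr(out, "constant") <- val
      out
    } else if (is.function(f)) {
      f
    } else {
      stop("'", name, "' must be a single number or a function on [-h, 0]")
    }
  }
  psi_f <- as_hist(psi, "psi")
  chk <- psi_f(seq(-h, 0, length.out = 41))
  if (any(!is.finite(chk)) || any(chk < 0)) {
    stop("mature-cell history 'psi' must be finite and nonnegative on [-h, 0]")
  }
  structure(list(phi = as_hist(phi, "phi"), psi = psi_f, h = h),
            class = "history_pair")
}

hist_constant <- function(f) attr(f, "constant")

# internal constructor skipping the admissibility scan (hot paths)
new_history_pair <- function(phi, psi, h) {
  structure(list(phi = phi, psi = psi, h = h), class = "history_pair")
}

# threshold delay for a constant mature-cell history: tau(v) solves
# integral_{x1}^{x2} dx / g(x, v) (g positive, so y is a strict bijection)
tau_constant_history <- function(v, cfg) {
  mat <- cfg$mat
  if (g_is_constant(mat)) {
    return((mat$x2 - mat$x1) / g_rate(mat$x1, 0, mat))
  }
  stats::integrate(function(x) 1 / g_rate(x, v, mat), mat$x1, mat$x2,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# Gauss-Legendre quadrature of f over [a, b] (f vectorised)
gl_quad <- function(f, a, b, n = 40) {
  if (b <= a) return(0)
  gl <- pracma::gaussLegendre(n, a, b)
  sum(gl$w * f(gl$x))
}

#' Maturity trajectory and threshold delay
#'
#' `maturity_trajectory()` solves the backward maturity problem
#' `y'(s) = -g(y(s), psi(-s))`, `y(0) = x2`, until `y` crosses `x1`; the
#' crossing time is the threshold delay `tau(psi)`, the time a progenitor
#' cell needed to mature from `x1` to `x2`.  `threshold_delay()` returns just
#' `tau`.
#'
#' Three evaluation routes are used, matching the structure of `g`:
#' a constant `g` gives `tau = (x2 - x1)/g` in closed form; a maturity-
#' independent `g(v)` reduces the threshold condition to the integral
#' equation `int_{-tau}^0 g(psi(theta)) dtheta = x2 - x1`, solved by Brent's
#' method on Gauss-Legendre quadrature; the general case is integrated with
#' an adaptive solver with event detection on the crossing.
#'
#' @param psi Mature-cell history: a constant, a function on `[-h, 0]`, or a
#'   [history_pair()] (its `psi` component is used).
#' @param cfg A [model_config()] object.
#' @param h History horizon; defaults to `cfg$h`.
#' @param with_integral If `TRUE`, also accumulate
#'   `int_0^tau (d - D1g)(y(s), psi(-s)) ds` (the exponent of the dilation
#'   factor in the delayed term) along the trajectory.
#' @param check Validate nonnegativity of the history (see [q_rate()]).
#' @return `maturity_trajectory()` returns a list with elements `tau`, `y`
#'   (a function of `s` on `[0, tau]`), `exp_integral` and `solver`;
#'   `threshold_delay()` returns the scalar `tau`.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0,(px)_1")  # constant g = 0.4
#' threshold_delay(0.6, cfg)               # (x2 - x1)/g = 2.5
#' @export
maturity_trajectory <- function(psi, cfg, h = NULL, with_integral = FALSE,
                                check = TRUE) {
  if (inherits(psi, "history_pair")) {
    if (is.null(h)) h <- psi$h
    psi <- psi$psi
  }
  if (is.null(h)) h <- cfg$h
  mat <- cfg$mat
  delta <- mat$x2 - mat$x1
  need_int <- with_integral && !(cfg$d$zero && g_is_x_independent(mat))

  if (is.numeric(psi) && length(psi) == 1) {
    v <- psi
    if (check) check_v(v)
    tau <- tau_constant_history(v, cfg)
    if (tau >= h) stop("horizon error: threshold delay ", format(tau),
                       " does not fit below h = ", format(h))
    yfun <- traj_constant_v(v, tau, cfg)
    ei <- if (need_int) {
      dv <- rate_derivatives(cfg)
      gl_quad(function(s) cfg$d$fun(yfun(s), v) - dv$D1g(yfun(s), v), 0, tau, 64)
    } else 0
    return(list(tau = tau, y = yfun, exp_integral = ei, solver = "constant-history"))
  }

  stopifnot(is.function(psi))
  if (g_is_constant(mat) && cfg$d$zero) {
    # tau does not depend on the history at all
    gv <- g_rate(mat$x1, 0, mat)
    tau <- delta / gv
    if (tau >= h) stop("horizon error: threshold delay ", format(tau),
                       " does not fit below h = ", format(h))
    return(list(tau = tau, y = function(s) mat$x2 - gv * s,
                exp_integral = 0, solver = "constant-g"))
  }
  if (g_is_x_independent(mat)) {
    gv <- function(theta) g_rate(mat$x1, psi(theta), mat, check = check)
    G <- function(tau) gl_quad(gv, -tau, 0, 48) - delta
    gh <- G(h)
    if (gh < 0) stop("horizon error: maturity does not cross x1 by s = h")
    tau <- stats::uniroot(G, c(0, h), f.lower = -delta, f.upper = gh,
                          tol = 1e-14)$root
    # explicit trajectory: y(s) = x2 - int_{-s}^0 g(psi(theta)) dtheta
    yfun <- function(s) {
      vapply(s, function(si) mat$x2 - gl_quad(gv, -si, 0, 48), numeric(1))
    }
    ei <- if (need_int) {
      gl_quad(function(s) cfg$d$fun(yfun(s), psi(-s)), 0, tau, 64)
    } else 0
    return(list(tau = tau, y = yfun, exp_integral = ei, solver = "integral-condition"))
  }

  # general state- and maturity-dependent g: adaptive solver, root on y = x1
  dv <- if (need_int) rate_derivatives(cfg) else NULL
  deriv <- function(s, y, parms) {
    vv <- if (check) max(psi(-s), 0) else psi(-s)
    dy <- -g_rate(y[1], vv, mat, x_tol = 0.05, check = check)
    dz <- if (need_int) cfg$d$fun(y[1], vv) - dv$D1g(y[1], vv) else 0
    list(c(dy, dz))
  }
  root <- function(s, y, parms) y[1] - mat$x1
  times <- seq(0, h, length.out = 241)
  sol <- deSolve::lsodar(y = c(mat$x2, 0), times = times, func = deriv,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-12, atol = 1e-12)
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0) {
    stop("horizon error: maturity does not cross x1 by s = h")
  }
  tau <- troot[1]
  keep <- sol[, 1] <= tau
  ss <- sol[keep, 1]; ys <- sol[keep, 2]; zs <- sol[keep, 3]
  if (ss[length(ss)] < tau) {  # ensure the crossing point itself is a knot
    ss <- c(ss, tau); ys <- c(ys, mat$x1); zs <- c(zs, sol[nrow(sol), 3])
  }
  yspl <- stats::splinefun(ss, ys, method = "fmm")
  yfun <- function(s) pmin(pmax(yspl(s), mat$x1), mat$x2)
  ei <- if (need_int) zs[length(zs)] else 0
  list(tau = tau, y = yfun, exp_integral = ei, solver = "ode-event")
}

# trajectory for constant history v: dense solve of y' = -g(y, v)
traj_constant_v <- function(v, tau, cfg) {
  mat <- cfg$mat
  if (g_is_x_independent(mat)) {
    gv <- g_rate(mat$x1, v, mat)
    return(function(s) mat$x2 - gv * s)
  }
  times <- seq(0, tau, length.out = 201)
  sol <- deSolve::lsoda(y = c(y = mat$x2), times = times,
                        func = function(s, y, p) {
                          list(-g_rate(y[1], v, mat, x_tol = 0.05, check = FALSE))
                        },
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
  yspl <- stats::splinefun(sol[, 1], sol[, 2], method = "fmm")
  function(s) pmin(pmax(yspl(s), mat$x1), mat$x2)
}

#' @rdname maturity_trajectory
#' @export
threshold_delay <- function(psi, cfg, h = NULL) {
  maturity_trajectory(psi, cfg, h = h)$tau
}

#' Right-hand-side functional of the delay system
#'
#' Evaluates `F = (F1, F2)` at a history pair: `F1 = q(psi(0)) phi(0)` and
#' `F2 = gamma(psi(-tau)) g(x2, psi(0)) phi(-tau) / g(x1, psi(-tau)) *
#' exp(int_0^tau (d - D1g)(y(s), psi(-s)) ds) - mu psi(0)` with
#' `tau = tau(psi)` the threshold delay.  Constant histories satisfying the
#' equilibrium conditions give `F = (0, 0)`.
#'
#' @param state A [history_pair()], or anything accepted by it when `phi`
#'   and `psi` are passed separately via `history_pair()` first.
#' @param cfg A [model_config()] object.
#' @param check Validate nonnegativity of the history (see [q_rate()]).
#' @return Numeric vector `c(F1, F2)`.
#' @export
rhs_F <- function(state, cfg, check = TRUE) {
  stopifnot(inherits(state, "history_pair"))
  phi <- state$phi; psi <- state$psi
  traj <- maturity_trajectory(psi, cfg, h = state$h, with_integral = TRUE,
                              check = check)
  tau <- traj$tau
  mat <- cfg$mat
  psi0 <- psi(0); psit <- psi(-tau)
  F1 <- q_rate(psi0, cfg$stem, check = check) * phi(0)
  F2 <- gamma_rate(psit, cfg$stem, check = check) *
    g_rate(mat$x2, psi0, mat, check = check) * phi(-tau) /
    g_rate(mat$x1, psit, mat, check = check) * exp(traj$exp_integral) -
    cfg$stem$mu * psi0
  c(F1, F2)
}

#' Compatibility residual with the solution manifold
#'
#' The natural state space of the delay system is the set of continuously
#' differentiable history pairs whose derivative at `0` equals the
#' right-hand-side functional.  This returns the Euclidean norm of
#' `(phi'(0), psi'(0)) - F(phi, psi)`; it vanishes for states on the
#' solution manifold, in particular for segments of any solution after the
#' initial transient and for equilibrium histories.
#'
#' @param state A [history_pair()]; the derivative at `0` is taken one-sided
#'   from the left (fourth-order finite differences).
#' @param cfg A [model_config()] object.
#' @return Nonnegative scalar residual.
#' @export
solution_manifold_residual <- function(state, cfg) {
  stopifnot(inherits(state, "history_pair"))
  dleft <- function(f) {
    s <- 1e-3 * min(1, state$h)
    th <- -s * (0:4)
    sum(c(25, -48, 36, -16, 3) * f(th)) / (12 * s)
  }
  dp <- c(dleft(state$phi), dleft(state$psi))
  sqrt(sum((dp - rhs_F(state, cfg))^2))
}


## ---- time integration (method of steps) ------------------------------------

#' Integrate the delay system
#'
#' Advances the coupled stem/mature-cell system from an initial history by
#' the method of steps: a fixed-step fourth-order Runge-Kutta scheme whose
#' accepted steps are stored as cubic Hermite interpolants, so that the
#' right-hand side can evaluate the history at arbitrary lags in `(0, tau]`.
#' The threshold delay is recomputed from the current dense history at every
#' stage.
#'
#' @param init A [history_pair()] with the initial history on `[-h, 0]`.
#' @param cfg A [model_config()] object.
#' @param t_end Final time (> 0).
#' @param dt Step size; default `tau0 / 20` where `tau0` is the delay at the
#'   initial state, capped at `0.05`.  Must stay below the smallest delay
#'   encountered.
#' @return An object of class `sdde_solution`: a list with a tibble `path`
#'   (columns `t`, `w`, `v`), interpolants `w_fun`, `v_fun`, the
#'   configuration, and the final history (a [history_pair()]).
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0,(px)_1")
#' eq <- positive_equilibrium(cfg)
#' sol <- integrate_sdde(history_pair(eq$w, eq$v, cfg$h), cfg, t_end = 2)
#' max(abs(sol$path$v - eq$v))
#' @export
integrate_sdde <- function(init, cfg, t_end, dt = NULL) {
  stopifnot(inherits(init, "history_pair"), t_end > 0)
  h <- init$h
  tau0 <- threshold_delay(init$psi, cfg, h = h)
  if (is.null(dt)) dt <- min(0.05, tau0 / 20)
  n <- ceiling(t_end / dt)
  dt <- t_end / n

  # knot storage: value and derivative at accepted step endpoints
  ts <- numeric(n + 1); ws <- numeric(n + 1); vs <- numeric(n + 1)
  dws <- numeric(n + 1); dvs <- numeric(n + 1)
  ts[1] <- 0; ws[1] <- init$phi(0); vs[1] <- init$psi(0)
  k <- 1  # index of last accepted knot

  hermite <- function(tq, i, val, der) {
    # cubic Hermite on [ts[i], ts[i+1]] (extrapolates beyond when needed)
    t0 <- ts[i]; t1 <- ts[i + 1]
    u <- (tq - t0) / (t1 - t0)
    h00 <- (1 + 2 * u) * (1 - u)^2; h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u);       h11 <- u^2 * (u - 1)
    h00 * val[i] + h10 * (t1 - t0) * der[i] +
      h01 * val[i + 1] + h11 * (t1 - t0) * der[i + 1]
  }
  hist_eval <- function(tq, init_f, val, der) {
    out <- numeric(length(tq))
    neg <- tq <= 0
    if (any(neg)) out[neg] <- init_f(pmax(tq[neg], -h))
    if (any(!neg)) {
      tq2 <- tq[!neg]
      i <- pmin(pmax(findInterval(tq2, ts[seq_len(k)]), 1), max(k - 1, 1))
      out[!neg] <- vapply(seq_along(tq2), function(j) {
        hermite(tq2[j], i[j], val, der)
      }, numeric(1))
    }
    out
  }

  rhs_at <- function(t, w, v) {
    # history accessors: stored knots for positive times, initial data before 0;
    # psi(0)/phi(0) are the current stage values, supplied directly
    phi_t <- function(theta) {
      ifelse(theta >= 0, w, hist_eval(t + theta, init$phi, ws, dws))
    }
    psi_t <- function(theta) {
      ifelse(theta >= 0, v,
             pmax(hist_eval(t + theta, init$psi, vs, dvs), 0))
    }
    vals <- rhs_F(new_history_pair(phi_t, psi_t, h), cfg)
    if (any(!is.finite(vals))) {
      stop("integration abort: state left the admissible domain at t = ",
           format(t))
    }
    vals
  }

  f0 <- rhs_at(0, ws[1], vs[1])
  dws[1] <- f0[1]; dvs[1] <- f0[2]
  for (i in seq_len(n)) {
    t0 <- ts[i]; w0 <- ws[i]; v0 <- vs[i]
    k1v <- c(dws[i], dvs[i])
    k2v <- rhs_at(t0 + dt / 2, w0 + dt / 2 * k1v[1], max(v0 + dt / 2 * k1v[2], 0))
    k3v <- rhs_at(t0 + dt / 2, w0 + dt / 2 * k2v[1], max(v0 + dt / 2 * k2v[2], 0))
    k4v <- rhs_at(t0 + dt, w0 + dt * k3v[1], max(v0 + dt * k3v[2], 0))
    incr <- (k1v + 2 * k2v + 2 * k3v + k4v) / 6
    ts[i + 1] <- t0 + dt
    ws[i + 1] <- w0 + dt * incr[1]
    vs[i + 1] <- v0 + dt * incr[2]
    if (vs[i + 1] < 0) {
      stop("integration abort: mature-cell amount became negative at t = ",
           format(ts[i + 1]))
    }
    k <- i + 1
    fi <- rhs_at(ts[i + 1], ws[i + 1], vs[i + 1])
    dws[i + 1] <- fi[1]; dvs[i + 1] <- fi[2]
  }

  w_fun <- function(tq) hist_eval(tq, init$phi, ws, dws)
  v_fun <- function(tq) hist_eval(tq, init$psi, vs, dvs)
  final <- history_pair(function(theta) w_fun(t_end + theta),
                        function(theta) pmax(v_fun(t_end + theta), 0), h)
  structure(list(
    path = tibble::tibble(t = ts, w = ws, v = vs),
    w_fun = w_fun, v_fun = v_fun, dt = dt,
    cfg = cfg, final_state = final
  ), class = "sdde_solution")
}

#' @export
print.sdde_solution <- function(x, ...) {
  cat("Delay-system solution on [0,", format(max(x$path$t)), "],",
      nrow(x$path), "steps (dt =", format(x$dt), ")\n")
  print(utils::head(x$path, 3))
  cat("...\n")
  print(utils::tail(x$path, 2))
  invisible(x)
}

#' Residual of a computed solution
#'
#' Recomputes `(w'(t), v'(t)) - F(w_t, v_t)` at sampled times by finite
#' differences on the dense output; a small residual certifies that the
#' stored path solves the delay system.
#'
#' @param sol An `sdde_solution` from [integrate_sdde()].
#' @param t_sample Times at which to check; defaults to 20 interior points.
#' @return Tibble with columns `t`, `residual`.
#' @export
solution_residual <- function(sol, t_sample = NULL) {
  tmax <- max(sol$path$t)
  if (is.null(t_sample)) {
    t_sample <- seq(0.1 * tmax, tmax, length.out = 20)
  }
  res <- vapply(t_sample, function(tt) {
    st <- history_pair(function(th) sol$w_fun(tt + th),
                       function(th) pmax(sol$v_fun(tt + th), 0),
                       sol$cfg$h)
    solution_manifold_residual(st, sol$cfg)
  }, numeric(1))
  tibble::tibble(t = t_sample, residual = res)
}
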