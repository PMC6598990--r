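# Pseudospectral reduction: Chebyshev-extremal collocation on [-h, 0],
# barycentric interpolation, differentiation matrix, the 2(M+1)-dimensional
# ODE system, and Jacobian eigenvalues approximating characteristic roots.

#' Chebyshev collocation mesh
#'
#' Builds the discretisation used to project histories onto polynomials of
#' degree `M`: the Chebyshev extremal nodes
#' `theta_j = (h/2) (cos(j pi / M) - 1)`, `j = 0, ..., M` (so `theta_0 = 0`
#' and `theta_M = -h`), the associated differentiation matrix and the
#' barycentric interpolation weights.
#'
#' @param M Discretisation index (>= 1).
#' @param h Interval length (> 0); the mesh spans `[-h, 0]`.
#' @return An object of class `cheb_disc` with elements `M`, `h`, `nodes`,
#'   `D` (differentiation matrix) and `bary_w`.
#' @examples
#' d <- cheb_disc(2, 2)
#' d$nodes           # 0, -1, -2
#' @export
cheb_disc <- function(M, h) {
  if (M < 1) stop("discretisation index M must be at least 1")
  stopifnot(h > 0)
  nodes <- cheb_nodes(M, h)
  # standard differentiation matrix on x_j = cos(j pi / M), mapped by
  # theta = (h/2)(x - 1)  =>  D_theta = (2/h) D_x
  x <- cos(seq(0, M) * pi / M)
  c_j <- c(2, rep(1, M - 1), 2) * (-1)^(0:M)
  X <- outer(x, x, "-")
  D <- outer(c_j, c_j, "/") / (X + diag(M + 1))
  diag(D) <- 0
  diag(D) <- -rowSums(D)
  D <- (2 / h) * D
  bw <- c(0.5, rep(1, M - 1), 0.5) * (-1)^(0:M)
  structure(list(M = M, h = h, nodes = nodes, D = D, bary_w = bw),
            class = "cheb_disc")
}

#' @rdname cheb_disc
#' @export
cheb_nodes <- function(M, h) {
  if (M < 1) stop("discretisation index M must be at least 1")
  (h / 2) * (cos(seq(0, M) * pi / M) - 1)
}

#' @export
print.cheb_disc <- function(x, ...) {
  cat("Chebyshev collocation mesh: M =", x$M, "on [", -x$h, ", 0]\n")
  invisible(x)
}

#' Differentiation matrix
#'
#' Returns the `(M+1) x (M+1)` matrix whose entry `(k, j)` is the derivative
#' of the j-th Lagrange basis polynomial at the k-th node; applied to nodal
#' values it differentiates the interpolating polynomial exactly.
#'
#' @param disc A [cheb_disc()].
#' @return Numeric matrix.
#' @export
diff_matrix <- function(disc) disc$D

#' Barycentric evaluation of the interpolant
#'
#' Evaluates the degree-`M` polynomial interpolating `values` at the mesh
#' nodes, using the numerically stable barycentric formula; exact at the
#' nodes.
#'
#' @param values Nodal values (length `M + 1`).
#' @param disc A [cheb_disc()].
#' @param theta Evaluation points in `[-h, 0]` (a small tolerance outside is
#'   permitted for solver overshoot).
#' @return Numeric vector of interpolant values.
#' @export
interp_eval <- function(values, disc, theta) {
  if (any(theta < -disc$h * (1 + 1e-9) - 1e-12) || any(theta > 1e-12)) {
    stop("interpolation point outside [-h, 0]")
  }
  d <- outer(theta, disc$nodes, "-")
  hit <- abs(d) < 1e-14
  wd <- disc$bary_w / t(d)
  out <- as.vector(values %*% wd) / colSums(wd)
  if (any(hit)) {
    ih <- which(hit, arr.ind = TRUE)
    out[ih[, 1]] <- values[ih[, 2]]
  }
  out
}

#' Pseudospectral ODE system
#'
#' Assembles the `2(M+1)`-dimensional ODE system that approximates the delay
#' system: the nodal values `(w_0, ..., w_M, v_0, ..., v_M)` represent the
#' interpolating polynomials `W_M`, `V_M` on `[-h, 0]`; the derivative of the
#' node at `theta_0 = 0` is the right-hand-side functional applied to
#' `(W_M, V_M)` (including the threshold-delay machinery evaluated on the
#' interpolant), and the remaining nodes evolve by exact differentiation of
#' the interpolants.
#'
#' @param cfg A [model_config()] object.
#' @param disc A [cheb_disc()]; for `type = "transformed"` its length must
#'   equal the fixed delay `x2 - x1`.
#' @param type `"sdde"` for the state-dependent system, `"transformed"` for
#'   the fixed-delay system obtained by the time transformation (requires a
#'   maturation rate independent of maturity).
#' @return An object of class `ps_system` with elements `rhs` (a function of
#'   the state vector), `disc`, `cfg`, `type`.
#' @export
ps_system <- function(cfg, disc, type = c("sdde", "transformed")) {
  type <- match.arg(type)
  M <- disc$M
  if (type == "transformed") {
    if (!g_is_x_independent(cfg$mat)) {
      stop("the time transformation requires g independent of maturity")
    }
    delta <- cfg$mat$x2 - cfg$mat$x1
    if (abs(disc$h - delta) > 1e-12) {
      stop("transformed system requires a mesh on [-delta, 0], delta = ",
           format(delta))
    }
  }
  rhs <- function(u) {
    W <- u[1:(M + 1)]; V <- u[(M + 2):(2 * (M + 1))]
    phiM <- function(theta) interp_eval(W, disc, theta)
    psiM <- function(theta) interp_eval(V, disc, theta)
    Fv <- if (type == "sdde") {
      rhs_F(new_history_pair(phiM, psiM, disc$h), cfg, check = FALSE)
    } else {
      transformed_rhs_G(new_history_pair(phiM, psiM, disc$h), cfg,
                        check = FALSE)
    }
    c(Fv[1], (disc$D %*% W)[-1], Fv[2], (disc$D %*% V)[-1])
  }
  structure(list(rhs = rhs, disc = disc, cfg = cfg, type = type),
            class = "ps_system")
}

#' Assemble the right-hand side of the reduced ODE system
#'
#' @param u State vector `(w_0..w_M, v_0..v_M)`.
#' @param sys A [ps_system()].
#' @return Derivative vector of length `2(M+1)`.
#' @export
assemble_rhs <- function(u, sys) sys$rhs(u)

#' Discretised equilibrium
#'
#' A constant nodal state: every node carries the equilibrium values; the
#' reduced system's right-hand side vanishes there.
#'
#' @param eq An `equilibrium`.
#' @param disc A [cheb_disc()].
#' @return State vector of length `2(M+1)`.
#' @export
discrete_equilibrium <- function(eq, disc) {
  c(rep(eq$w, disc$M + 1), rep(eq$v, disc$M + 1))
}

#' Jacobian of the reduced system
#'
#' The differentiation rows are linear and copied exactly; only the two
#' functional rows are differentiated numerically, by fourth-order central
#' differences (Richardson-extrapolated), so that the Jacobian error stays
#' near rounding level.
#'
#' @param sys A [ps_system()].
#' @param u0 State vector at which to linearise (usually a
#'   [discrete_equilibrium()]).
#' @param fd_step Relative finite-difference step.
#' @param fd_order Order of the central difference: 4 (default; near
#'   rounding-level accuracy) or 2 (half the cost, ~1e-7 accuracy; enough
#'   for boundary tracing).
#' @return A `2(M+1) x 2(M+1)` matrix.
#' @export
ps_jacobian <- function(sys, u0, fd_step = 1e-3, fd_order = 4) {
  disc <- sys$disc; M <- disc$M
  n <- 2 * (M + 1)
  J <- matrix(0, n, n)
  # exact differentiation rows
  J[2:(M + 1), 1:(M + 1)] <- disc$D[-1, ]
  J[(M + 3):n, (M + 2):n] <- disc$D[-1, ]
  F_of <- function(u) {
    full <- sys$rhs(u)
    c(full[1], full[M + 2])
  }
  for (k in seq_len(n)) {
    s <- fd_step * max(1, abs(u0[k]))
    up <- function(d) { u <- u0; u[k] <- u[k] + d; F_of(u) }
    der <- if (fd_order >= 4) {
      (-up(2 * s) + 8 * up(s) - 8 * up(-s) + up(-2 * s)) / (12 * s)
    } else {
      (up(s) - up(-s)) / (2 * s)
    }
    J[1, k] <- der[1]
    J[M + 2, k] <- der[2]
  }
  J
}

#' Eigenvalues of the reduced system at an equilibrium
#'
#' Computes the spectrum of the Jacobian of the pseudospectral ODE system at
#' a discretised equilibrium.  The rightmost eigenvalues approximate the
#' characteristic roots of the delay system with spectral accuracy in `M`.
#' With `filter = TRUE` the computation is repeated at `M + 5` and an
#' eigenvalue is flagged `physical` when it reappears within `filter_tol`;
#' discretisation artifacts move with `M` and are flagged out.
#'
#' @param cfg A [model_config()] object.
#' @param eq Equilibrium to linearise at; defaults to the positive one.
#' @param M Discretisation index (default 15).
#' @param h Mesh length; defaults to twice the equilibrium threshold delay
#'   (`"sdde"`) or to the fixed delay (`"transformed"`).
#' @param type Passed to [ps_system()].
#' @param filter Flag physical eigenvalues by an `M` vs `M + 5` comparison.
#' @param filter_tol Matching tolerance for the filter.
#' @param fd_order Passed to [ps_jacobian()].
#' @return A tibble of class `sdde_spectrum` with columns `re`, `im`,
#'   `physical`, sorted by decreasing real part; attributes `M`, `h`, `type`.
#' @examples
#' cfg <- scenario("(s)_d,(pv)_0,(px)_1")
#' sp <- ps_eigenvalues(cfg, trivial_equilibrium(cfg), M = 10)
#' sp[1:2, ]   # leading roots near q(0) = 0.6 and -mu = -1
#' @export
ps_eigenvalues <- function(cfg, eq = NULL, M = 15, h = NULL,
                           type = c("sdde", "transformed"),
                           filter = FALSE, filter_tol = 1e-3, fd_order = 4) {
  type <- match.arg(type)
  if (is.null(eq)) eq <- positive_equilibrium(cfg)
  if (is.null(h)) {
    h <- if (type == "transformed") cfg$mat$x2 - cfg$mat$x1 else 2 * eq$tau_eq
  }
  vals_at <- function(MM) {
    disc <- cheb_disc(MM, h)
    sys <- ps_system(cfg, disc, type = type)
    eigen(ps_jacobian(sys, discrete_equilibrium(eq, disc), fd_order = fd_order),
          only.values = TRUE)$values
  }
  ev <- vals_at(M)
  physical <- rep(TRUE, length(ev))
  if (filter) {
    ev2 <- vals_at(M + 5)
    physical <- vapply(ev, function(z) {
      min(abs(z - ev2)) < filter_tol * (1 + abs(z))
    }, logical(1))
  }
  ord <- order(-Re(ev), abs(Im(ev)))
  out <- tibble::tibble(re = Re(ev)[ord], im = Im(ev)[ord],
                        physical = physical[ord])
  class(out) <- c("sdde_spectrum", class(out))
  attr(out, "M") <- M; attr(out, "h") <- h; attr(out, "type") <- type
  out
}

#' Integrate the reduced ODE system
#'
#' Time integration of the pseudospectral ODE system with an adaptive
#' solver; the value at the node `theta_0 = 0` approximates the solution of
#' the delay system.
#'
#' @param sys A [ps_system()].
#' @param u0 Initial nodal state; e.g. a [discrete_equilibrium()] or nodal
#'   samples of an initial history.
#' @param t_end Final time.
#' @param n_out Number of output times.
#' @param rtol,atol Solver tolerances.
#' @return Tibble with columns `t`, `w`, `v` (node-0 values) plus the full
#'   nodal matrix as attribute `"states"`.
#' @export
ps_integrate <- function(sys, u0, t_end, n_out = 101,
                         rtol = 1e-8, atol = 1e-8) {
  M <- sys$disc$M
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = u0, times = times,
                      func = function(t, y, p) list(sys$rhs(y)),
                      parms = NULL, rtol = rtol, atol = atol, method = "ode45")
  out <- tibble::tibble(t = sol[, 1], w = sol[, 2], v = sol[, M + 3])
  attr(out, "states") <- sol[, -1, drop = FALSE]
  out
}
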