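# Numerical two-parameter stability boundaries in the (mu, p) plane:
# rightmost-eigenvalue evaluation, crossing detection in p at fixed mu,
# boundary tracing with a secant predictor, and cross-method validation.

#' Configuration factory for a scenario family
#'
#' Returns a function of `(mu, p)` producing the [scenario()] configuration,
#' for use with the boundary-tracing routines.
#'
#' @param label Scenario label, see [scenario()].
#' @param g0 Baseline maturation speed.
#' @param ... Further arguments passed to [scenario()] (e.g. `k_a`, `k_p`).
#' @return A function `function(mu, p) -> model_config`.
#' @export
scenario_family <- function(label, g0 = 0, ...) {
  force(label); force(g0)
  dots <- list(...)
  function(mu, p) {
    do.call(scenario, c(list(label = label, p = p, mu = mu, g0 = g0), dots))
  }
}

#' Rightmost characteristic root at a parameter point
#'
#' Computes the positive equilibrium of `cfg_fn(mu, p)` and returns the
#' eigenvalue of the pseudospectral Jacobian with maximal real part (with
#' optional filtering of discretisation artifacts).
#'
#' @param mu,p Parameter point; the positive equilibrium must exist
#'   (`p` above the transcritical threshold).
#' @param cfg_fn A configuration factory, see [scenario_family()].
#' @param M Discretisation index.
#' @param type `"sdde"` or `"transformed"` (the latter requires `g`
#'   independent of maturity; its roots are scaled by `1/g(v)` but carry the
#'   same stability verdict).
#' @param filter Use the `M` vs `M + 5` physical filter.
#' @param fd_order Jacobian finite-difference order; the default 2 locates
#'   boundaries to ~1e-7, ample for tracing (see [ps_jacobian()]).
#' @return A complex number.
#' @export
rightmost_root <- function(mu, p, cfg_fn, M = 15,
                           type = c("sdde", "transformed"), filter = FALSE,
                           fd_order = 2) {
  type <- match.arg(type)
  cfg <- cfg_fn(mu, p)
  eq <- positive_equilibrium(cfg)
  sp <- ps_eigenvalues(cfg, eq, M = M, type = type, filter = filter,
                       fd_order = fd_order)
  if (filter) sp <- sp[sp$physical, ]
  complex(real = sp$re[1], imaginary = abs(sp$im[1]))
}

#' Destabilisation point in p at fixed mu
#'
#' Searches for the division rate `p` at which the rightmost characteristic
#' root crosses the imaginary axis, at fixed mature-cell mortality `mu`:
#' scans `Re lambda_max(p)` for a sign change over `p_range` and refines it
#' by Brent bisection until the residual real part is below `re_tol`.  A
#' missing sign change is reported as not found (the equilibrium is stable,
#' or unstable, for every `p` scanned).
#'
#' @param mu Mature-cell mortality.
#' @param cfg_fn Configuration factory, see [scenario_family()].
#' @param p_range Search interval for `p`; the lower end is raised above the
#'   transcritical threshold automatically.
#' @param M Discretisation index.
#' @param type Passed to [rightmost_root()].
#' @param n_scan Number of scan points (log-spaced).
#' @param re_tol Certificate bound on `|Re lambda_max|` at the crossing.
#' @return A list with `found`, and when found `p`, `omega`
#'   (imaginary part of the crossing pair, in the time scale of `type`),
#'   `re_residual`.
#' @export
find_crossing_p <- function(mu, cfg_fn, p_range = c(NA, 50), M = 15,
                            type = "sdde", n_scan = 12, re_tol = 1e-8) {
  p_star <- existence_threshold(cfg_fn(mu, max(p_range[2], 1))$stem)
  lo <- if (is.na(p_range[1])) 1.02 * p_star else max(p_range[1], 1.02 * p_star)
  hi <- p_range[2]
  if (hi <= lo) stop("empty search range above the transcritical threshold")
  f <- function(p) Re(rightmost_root(mu, p, cfg_fn, M = M, type = type))
  ps <- exp(seq(log(lo), log(hi), length.out = n_scan))
  fs <- vapply(ps, f, numeric(1))
  ix <- which(fs[-length(fs)] * fs[-1] < 0)
  if (length(ix) == 0) {
    return(list(found = FALSE, p = NA_real_, omega = NA_real_,
                re_residual = NA_real_, sign = sign(fs[1])))
  }
  i <- ix[1]
  root <- stats::uniroot(f, c(ps[i], ps[i + 1]),
                         f.lower = fs[i], f.upper = fs[i + 1], tol = 1e-11)
  z <- rightmost_root(mu, root$root, cfg_fn, M = M, type = type)
  if (abs(Re(z)) > re_tol) {
    warning("crossing residual ", format(abs(Re(z))), " above tolerance")
  }
  list(found = TRUE, p = root$root, omega = abs(Im(z)), re_residual = abs(Re(z)))
}

#' Crossing point from the closed-form boundary
#'
#' For a configuration in the fixed-delay family (constant `g` not coupled
#' to `p`, zero production, unregulated self-renewal), inverts the analytic
#' boundary at fixed `mu`: finds the frequency with `m(omega) = mu * tau` on
#' the parametrisation interval (where `m` is strictly increasing) and maps
#' `r(omega)` to `p`.  Returns `found = FALSE` when the crossing lies outside
#' the existence region (`r >= 1`: stable for every `p`).
#'
#' @param mu Mature-cell mortality.
#' @param cfg Any configuration of the family (used for `tau`, `mu_w`, `a`).
#' @return A list with `found`, `p`, `omega` (unscaled crossing frequency
#'   `omega_scaled / tau`), `r`, `m`.
#' @export
analytic_crossing_p <- function(mu, cfg) {
  stem <- cfg$stem
  if (!g_is_constant(cfg$mat)) stop("analytic boundary requires constant g")
  if (stem$k_a != 0) stop("analytic boundary requires k_a = 0")
  if (!cfg$d$zero) stop("analytic boundary requires zero production")
  tau <- (cfg$mat$x2 - cfg$mat$x1) / g_rate(cfg$mat$x1, 0, cfg$mat)
  eta <- stem$mu_w * tau
  m_target <- mu * tau
  iv <- boundary_interval(eta)
  mfun <- function(om) boundary_point(om, eta)$m - m_target
  om <- stats::uniroot(mfun, c(iv[1] + 1e-9, iv[2] - 1e-9), tol = 1e-13)$root
  bp <- boundary_point(om, eta)
  if (bp$r >= 1 || bp$r <= 0) {
    return(list(found = FALSE, p = NA_real_, omega = om / tau,
                r = bp$r, m = bp$m))
  }
  p <- to_mu_p(bp$m, bp$r, tau = tau, mu_w = stem$mu_w, a = stem$a)$p
  list(found = TRUE, p = p, omega = om / tau, r = bp$r, m = bp$m)
}

#' Trace a stability boundary over a mortality grid
#'
#' Walks `mu` over a grid and locates the destabilisation point in `p` at
#' each value, reusing the previous crossings as a secant predictor for the
#' next bracket (with widening on failure).  Points where no crossing exists
#' in range are recorded as not found.
#'
#' @param cfg_fn Configuration factory, see [scenario_family()].
#' @param mu_grid Ordered vector of `mu` values.
#' @param M Discretisation index.
#' @param type Passed to [rightmost_root()].
#' @param p_max Upper end of the `p` search window.
#' @param re_tol Crossing certificate tolerance.
#' @return Tibble of class `boundary_trace` with columns `mu`, `p`, `omega`,
#'   `re_residual`, `found`.
#' @examples
#' \donttest{
#' fam <- scenario_family("(s)_d,(pv)_0,(px)_1", g0 = 2/3 - 0.4)
#' trace_boundary(fam, mu_grid = c(1.5, 2), M = 8)
#' }
#' @export
trace_boundary <- function(cfg_fn, mu_grid, M = 15, type = "sdde",
                           p_max = 50, re_tol = 1e-8) {
  rows <- vector("list", length(mu_grid))
  prev <- list()  # last found crossings, for the secant predictor
  for (i in seq_along(mu_grid)) {
    mu <- mu_grid[i]
    p_rng <- c(NA, p_max)
    if (length(prev) >= 2) {
      pr <- prev[[length(prev)]]; pr2 <- prev[[length(prev) - 1]]
      pred <- pr$p + (pr$p - pr2$p) / (pr$mu - pr2$mu) * (mu - pr$mu)
      if (is.finite(pred) && pred > 0) p_rng <- c(pred / 2, min(2 * pred, p_max))
    } else if (length(prev) == 1) {
      p_rng <- c(prev[[1]]$p / 2, min(2 * prev[[1]]$p, p_max))
    }
    cr <- find_crossing_p(mu, cfg_fn, p_range = p_rng, M = M, type = type,
                          re_tol = re_tol)
    if (!cr$found && !is.na(p_rng[1])) {
      # widen back to the full window before giving up
      cr <- find_crossing_p(mu, cfg_fn, p_range = c(NA, p_max), M = M,
                            type = type, re_tol = re_tol)
    }
    if (cr$found) prev <- c(prev, list(list(mu = mu, p = cr$p)))
    rows[[i]] <- tibble::tibble(mu = mu, p = cr$p, omega = cr$omega,
                                re_residual = cr$re_residual, found = cr$found)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("boundary_trace", class(out))
  out
}

#' Cross-method validation of a stability boundary
#'
#' Computes the destabilisation point `p(mu)` by every method the scenario
#' admits -- closed-form boundary (fixed-delay family), pseudospectral
#' eigenvalues of the state-dependent system, and pseudospectral eigenvalues
#' of the time-transformed fixed-delay system -- and reports the pairwise
#' maximal relative discrepancies.  When `mu_values` is omitted and the
#' analytic route applies, the values are sampled along the analytic curve
#' inside the existence region (with `p <= p_cap`).
#'
#' @param cfg_fn Configuration factory, see [scenario_family()].
#' @param mu_values Mortality values at which to compare; optional when the
#'   analytic route applies.
#' @param n_mu Number of sampled values when `mu_values` is omitted.
#' @param M Discretisation index.
#' @param p_cap,mu_cap Caps on `p` and `mu` for the sampled comparison
#'   window (mirroring the search window of the numerical study).
#' @param methods Methods to attempt; inapplicable ones are dropped with a
#'   note in the output.
#' @return A list of class `method_comparison`: tibble `points` (one row per
#'   `mu`, one column per method), `pairwise` (max relative discrepancies),
#'   `methods`, `skipped`.
#' @export
compare_methods <- function(cfg_fn, mu_values = NULL, n_mu = 20, M = 15,
                            p_cap = 50, mu_cap = 50,
                            methods = c("analytic", "pseudospectral",
                                        "transformed")) {
  methods <- match.arg(methods, several.ok = TRUE)
  cfg_probe <- cfg_fn(1, 2)
  skipped <- character()
  if ("analytic" %in% methods) {
    ok <- g_is_constant(cfg_probe$mat) && cfg_probe$stem$k_a == 0 &&
      cfg_probe$d$zero &&
      abs(g_rate(0.5 * (cfg_probe$mat$x1 + cfg_probe$mat$x2), 0,
                 cfg_fn(1, 3)$mat) -
          g_rate(0.5 * (cfg_probe$mat$x1 + cfg_probe$mat$x2), 0,
                 cfg_probe$mat)) < 1e-14
    if (!ok) {
      skipped <- c(skipped, "analytic (fixed-delay hypotheses not met)")
      methods <- setdiff(methods, "analytic")
    }
  }
  if ("transformed" %in% methods && !g_is_x_independent(cfg_probe$mat)) {
    skipped <- c(skipped, "transformed (g depends on maturity)")
    methods <- setdiff(methods, "transformed")
  }
  if (length(methods) == 0) stop("no applicable method")

  if (is.null(mu_values)) {
    if (!("analytic" %in% methods)) {
      stop("mu_values must be given when the analytic route does not apply")
    }
    tau <- (cfg_probe$mat$x2 - cfg_probe$mat$x1) /
      g_rate(cfg_probe$mat$x1, 0, cfg_probe$mat)
    eta <- cfg_probe$stem$mu_w * tau
    bc <- boundary_curve(eta, n_points = 800)
    keep <- bc$r > 0 & bc$r < 1 - cfg_probe$stem$mu_w /
      ((2 * cfg_probe$stem$a - 1) * p_cap) &
      bc$m > 1e-3 & bc$m / tau <= mu_cap
    if (!any(keep)) stop("analytic boundary has no physical points below p_cap")
    idx <- which(keep)
    sel <- idx[unique(round(seq(1, length(idx), length.out = n_mu)))]
    mu_values <- bc$m[sel] / tau
  }

  cols <- list(mu = mu_values)
  for (mth in methods) {
    cols[[paste0("p_", mth)]] <- vapply(seq_along(mu_values), function(i) {
      mu <- mu_values[i]
      if (mth == "analytic") {
        cr <- analytic_crossing_p(mu, cfg_probe)
        return(if (cr$found) cr$p else NA_real_)
      }
      type <- if (mth == "transformed") "transformed" else "sdde"
      guess <- if (!is.null(cols$p_analytic)) cols$p_analytic[i] else NA
      rng <- if (is.finite(guess)) c(guess / 1.6, min(1.6 * guess, 4 * p_cap))
             else c(NA, p_cap)
      ns <- if (is.finite(guess)) 4 else 12
      cr <- find_crossing_p(mu, cfg_fn, p_range = rng, M = M, type = type,
                            n_scan = ns)
      if (!cr$found && is.finite(guess)) {
        cr <- find_crossing_p(mu, cfg_fn, p_range = c(NA, 4 * p_cap),
                              M = M, type = type)
      }
      if (cr$found) cr$p else NA_real_
    }, numeric(1))
  }
  points <- tibble::as_tibble(cols)

  pcols <- paste0("p_", methods)
  pw <- list()
  if (length(pcols) > 1) {
    cmb <- utils::combn(pcols, 2)
    for (j in seq_len(ncol(cmb))) {
      x <- points[[cmb[1, j]]]; y <- points[[cmb[2, j]]]
      okp <- is.finite(x) & is.finite(y)
      pw[[paste(cmb[1, j], cmb[2, j], sep = " vs ")]] <-
        if (any(okp)) max(abs(x[okp] - y[okp]) / pmax(abs(x[okp]), abs(y[okp])))
        else NA_real_
    }
  }
  structure(list(points = points, pairwise = unlist(pw),
                 methods = methods, skipped = skipped),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Stability-boundary cross-validation (", nrow(x$points), " mu values)\n",
      sep = "")
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  if (length(x$pairwise)) {
    for (nm in names(x$pairwise)) {
      cat(sprintf("  %-38s max rel. discrepancy %.3g\n", nm, x$pairwise[nm]))
    }
  }
  invisible(x)
}
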