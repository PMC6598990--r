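# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for result objects
#'
#' `tidy()` returns one row per element (equilibrium, eigenvalue, boundary
#' point); `glance()` returns a one-row summary.
#'
#' @param x An `equilibrium`, `sdde_spectrum`, `sdde_solution`,
#'   `boundary_trace` or `method_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @name sddcell-tidiers
NULL

#' @rdname sddcell-tidiers
#' @export
tidy.sdde_spectrum <- function(x, ...) {
  tibble::tibble(re = x$re, im = x$im, physical = x$physical,
                 modulus = sqrt(x$re^2 + x$im^2))
}

#' @rdname sddcell-tidiers
#' @export
glance.sdde_spectrum <- function(x, ...) {
  ph <- x[x$physical, ]
  tibble::tibble(M = attr(x, "M"), h = attr(x, "h"), type = attr(x, "type"),
                 n_eigenvalues = nrow(x), n_physical = nrow(ph),
                 rightmost_re = ph$re[1], rightmost_im = ph$im[1],
                 stable = ph$re[1] < 0)
}

#' @rdname sddcell-tidiers
#' @export
tidy.sdde_solution <- function(x, ...) x$path

#' @rdname sddcell-tidiers
#' @export
glance.sdde_solution <- function(x, ...) {
  tibble::tibble(t_end = max(x$path$t), dt = x$dt,
                 w_final = x$path$w[nrow(x$path)],
                 v_final = x$path$v[nrow(x$path)])
}

#' @rdname sddcell-tidiers
#' @export
tidy.boundary_trace <- function(x, ...) tibble::as_tibble(x)

#' @rdname sddcell-tidiers
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points),
                 n_methods = length(x$methods),
                 max_pairwise_discrepancy =
                   if (length(x$pairwise)) max(x$pairwise) else NA_real_)
}

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: stability boundaries
#' in the scaled `(m, r)` or unscaled `(mu, p)` plane, spectra in the
#' complex plane, and solution paths over time.
#'
#' @param object A `boundary_curve`, `boundary_trace`, `sdde_spectrum` or
#'   `sdde_solution`.
#' @param plane For boundary curves, `"mr"` or `"mup"` (the latter requires
#'   the curve to carry unscaled coordinates).
#' @param ... Unused.
#' @return A ggplot object.
#' @name sddcell-plots
NULL

#' @rdname sddcell-plots
#' @export
autoplot.boundary_curve <- function(object, plane = c("mr", "mup"), ...) {
  plane <- match.arg(plane)
  eta <- attr(object, "eta")
  if (plane == "mup") {
    if (is.null(object$mu)) stop("curve carries no (mu, p) coordinates; ",
                                 "pass tau to boundary_curve()")
    df <- object[object$r > 0 & object$r < 1, ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$p)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "mature-cell mortality mu", y = "division rate p",
                    title = sprintf("Stability boundary (eta = %g)", eta),
                    subtitle = "equilibrium stable below the curve") +
      ggplot2::theme_minimal()
  } else {
    df <- object[object$r > 0, ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$r)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "m = mu tau", y = "r = 1 - mu_w / ((2a-1) p)",
                    title = sprintf("Scaled stability boundary (eta = %g)", eta)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname sddcell-plots
#' @export
autoplot.boundary_trace <- function(object, ...) {
  df <- object[object$found, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$p)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mature-cell mortality mu", y = "division rate p",
                  title = "Numerically traced stability boundary") +
    ggplot2::theme_minimal()
}

#' @rdname sddcell-plots
#' @export
autoplot.sdde_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$re, y = .data$im,
                               shape = .data$physical)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Re", y = "Im",
                  title = sprintf("Approximated characteristic roots (M = %d)",
                                  attr(object, "M"))) +
    ggplot2::theme_minimal()
}

#' @rdname sddcell-plots
#' @export
autoplot.sdde_solution <- function(object, ...) {
  df <- object$path
  long <- tibble::tibble(t = rep(df$t, 2),
                         amount = c(df$w, df$v),
                         compartment = rep(c("stem cells w", "mature cells v"),
                                           each = nrow(df)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$amount,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "cell amount") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
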