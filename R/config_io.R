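# Structured-text (YAML) configuration files and small report helpers.

#' Read a model configuration from a YAML file
#'
#' Two layouts are accepted.  A scenario file carries a single `scenario`
#' key plus optional overrides:
#' ```yaml
#' scenario: "(s)_d,(pv)_0,(px)_1"
#' p: 2
#' mu: 1
#' g0: 0
#' ```
#' A full file carries `stem`, `maturation` and optional `model` sections
#' whose keys mirror the arguments of [stem_params()], [maturation_params()]
#' and [model_config()]; profile entries (`a_u`, `p_u`) are scalars or
#' polynomial coefficient vectors.
#'
#' @param path Path to the YAML file.
#' @return A [model_config()].
#' @examples
#' path <- system.file("extdata", "scenario-sd-pv0-px1.yaml", package = "sddcell")
#' if (nzchar(path)) read_model_config(path)
#' @export
read_model_config <- function(path) {
  conf <- yaml::read_yaml(path)
  if (!is.null(conf$scenario)) {
    args <- conf[setdiff(names(conf), "scenario")]
    return(do.call(scenario, c(list(label = conf$scenario), args)))
  }
  if (is.null(conf$stem) || is.null(conf$maturation)) {
    stop("configuration must contain either a 'scenario' key or both ",
         "'stem' and 'maturation' sections")
  }
  st <- do.call(stem_params, conf$stem)
  mt_args <- conf$maturation
  for (nm in c("a_u", "p_u")) {
    if (!is.null(mt_args[[nm]])) mt_args[[nm]] <- unlist(mt_args[[nm]])
  }
  mt <- do.call(maturation_params, mt_args)
  h <- conf$model$h
  model_config(st, mt, h = h)
}

#' Equilibrium report
#'
#' Computes the trivial and (when it exists) positive equilibrium of a
#' configuration and returns a small report, suitable for serialisation.
#'
#' @param cfg A [model_config()].
#' @return A list with `exists` (positive equilibrium), `p_star`, `trivial`
#'   and `positive` (each a one-row tibble or `NULL`).
#' @export
equilibrium_report <- function(cfg) {
  ex <- q_rate(0, cfg$stem) > 0
  list(exists = ex,
       p_star = existence_threshold(cfg$stem),
       trivial = tidy(trivial_equilibrium(cfg)),
       positive = if (ex) tidy(positive_equilibrium(cfg)) else NULL)
}
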