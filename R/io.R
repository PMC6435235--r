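#' Read a model configuration file
#'
#' Loads a YAML configuration with sections `model` (parameters of
#' [two_sex_model()]), optional `mating` ([mating_spec()] fields),
#' optional `integrator` (`tol`, `t_max`, `checkpoint`, `rtol`,
#' `atol`), and optional `sweep` (named parameter grids for
#' [harvest_sweep()]). Unknown keys anywhere are rejected so that a
#' typo cannot silently skew results; all values are validated by the
#' constructors before any computation.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `model` (a `bmmr_model`), `integrator`
#'   (named list of [equilibrate()] settings), and `sweep` (named list
#'   of grids, or `NULL`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed_top <- c("model", "mating", "integrator", "sweep")
  bad <- setdiff(names(cfg), allowed_top)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$model)) stop("config must have a 'model' section")

  model_keys <- c("h", "mu_m1", "mu_f1", "mu_m2", "mu_f2", "alpha_m",
                  "alpha_f", "d", "k", "s1", "E", "s_h")
  bad <- setdiff(names(cfg$model), model_keys)
  if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))

  mating <- mating_spec("harmonic")
  if (!is.null(cfg$mating)) {
    mkeys <- c("family", "beta", "alpha", "scale")
    bad <- setdiff(names(cfg$mating), mkeys)
    if (length(bad)) stop("unknown mating key(s): ", paste(bad, collapse = ", "))
    mating <- do.call(mating_spec, cfg$mating)
  }

  integ <- list()
  if (!is.null(cfg$integrator)) {
    ikeys <- c("tol", "t_max", "checkpoint", "rtol", "atol")
    bad <- setdiff(names(cfg$integrator), ikeys)
    if (length(bad)) stop("unknown integrator key(s): ", paste(bad, collapse = ", "))
    integ <- cfg$integrator
  }

  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    bad <- setdiff(names(cfg$sweep), model_keys)
    if (length(bad)) stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "))
    sweep <- lapply(cfg$sweep, as.numeric)
  }

  model <- do.call(two_sex_model, c(cfg$model, list(mating = mating)))
  list(model = model, integrator = integ, sweep = sweep)
}

#' Write results to disk
#'
#' Serializes an equilibrium (JSON: `p_hat`, `lambda`, `w`, `s2`,
#' `prop_mated`, `converged`, `residual`, `t_final`), a sweep table or
#' any data frame (CSV), or a process matrix (labelled CSV). Output is
#' identical across repeated runs on identical inputs.
#'
#' @param x A `bmmr_equilibrium`, `bmmr_sweep`, data frame, or matrix.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`; default chosen from the object.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (inherits(x, "bmmr_equilibrium")) {
    if (is.null(format)) format <- "json"
    if (format == "json") {
      out <- list(p_hat = unname(x$p_hat), lambda = x$lambda,
                  w = unname(x$w), s2 = x$s2, prop_mated = x$prop_mated,
                  converged = x$converged, residual = x$residual,
                  t_final = x$t_final, stages = x$model$space$labels)
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(x$trajectory, path, row.names = FALSE)
    }
  } else if (is.data.frame(x)) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (is.matrix(x)) {
    utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  } else {
    stop("don't know how to write an object of class ",
         paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Built-in example configurations
#'
#' Named parameterizations of the worked examples: the monogamy
#' baseline, the monogamy harvest sweep, the unharvested polygyny grid,
#' the polygyny harvest grids at female-biased / unbiased / male-biased
#' harvest, and the harvest-intensity sweep at the four mating-system
#' corners (small/large harems crossed with persistent/transient
#' unions). All share the baseline vital rates: juvenile mortality 0.5,
#' adult mortality 0.1, maturation 0.5 for both sexes, `k = 20`,
#' `s1 = 0.5`.
#'
#' @param name One of `"fig3_monogamy"`, `"fig4_monogamy_sweep"`,
#'   `"fig7_polygyny_grid"`, `"fig8_harvest_grids"`, `"fig9_E_sweep"`.
#' @return A list with elements `model` (a `bmmr_model`) and `sweep`
#'   (named grid list or `NULL`), as from [read_model_config()].
#' @examples
#' fx <- model_fixture("fig3_monogamy")
#' fx$model$params$d
#' @export
model_fixture <- function(name = c("fig3_monogamy", "fig4_monogamy_sweep",
                                   "fig7_polygyny_grid",
                                   "fig8_harvest_grids", "fig9_E_sweep")) {
  name <- match.arg(name)
  base <- function(...) {
    two_sex_model(mu_m1 = 0.5, mu_f1 = 0.5, mu_m2 = 0.1, mu_f2 = 0.1,
                  alpha_m = 0.5, alpha_f = 0.5, k = 20, s1 = 0.5, ...)
  }
  d_grid <- seq(0, 2, by = 0.5)
  switch(name,
    fig3_monogamy = list(
      model = base(h = 1, d = 0.1, E = 0),
      sweep = NULL
    ),
    fig4_monogamy_sweep = list(
      model = base(h = 1, d = 0.1, E = 1),
      sweep = list(d = d_grid, s_h = seq(0, 1, by = 0.25))
    ),
    fig7_polygyny_grid = list(
      model = base(h = 2, d = 0, E = 0),
      sweep = list(h = 2:10, d = d_grid)
    ),
    fig8_harvest_grids = list(
      model = base(h = 2, d = 0, E = 1),
      sweep = list(h = 2:10, d = d_grid, s_h = c(0, 0.5, 1))
    ),
    fig9_E_sweep = list(
      model = base(h = 2, d = 0, E = 0),
      sweep = list(h = c(2, 10), d = c(0, 2), s_h = c(0, 0.5, 1),
                   E = seq(0, 1, by = 0.25))
    )
  )
}
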