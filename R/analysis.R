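#' Secondary sex ratio
#'
#' Proportion of adults that is male at composition `p`, counting the
#' adults inside unions through the stage content weights: a union with
#' a harem of `i` females contributes one male and `i` females.
#'
#' @param space A [stage_space()].
#' @param p Frequency (or density) vector over stages.
#' @return `s2` in `[0, 1]`.
#' @export
secondary_sex_ratio <- function(space, p) {
  stopifnot(inherits(space, "stage_space"))
  check_state(space, p, what = "p")
  males <- sum(space$adult_males * p)
  adults <- males + sum(space$adult_females * p)
  if (adults == 0) stop("no adults in 'p': secondary sex ratio undefined")
  males / adults
}

#' Proportion of mated adults
#'
#' Fraction of adult individuals that are inside a union (pair or
#' harem) rather than in the single stages `m2`, `f2`.
#'
#' @inheritParams secondary_sex_ratio
#' @return Fraction in `[0, 1]`.
#' @export
proportion_mated <- function(space, p) {
  stopifnot(inherits(space, "stage_space"))
  check_state(space, p, what = "p")
  content <- space$adult_males + space$adult_females
  adults <- sum(content * p)
  if (adults == 0) stop("no adults in 'p': proportion mated undefined")
  in_union <- seq_len(space$s) > 4L
  sum(content[in_union] * p[in_union]) / adults
}

#' Sweep harvest and mating-system parameters
#'
#' Runs the model to equilibrium over the Cartesian grid of the supplied
#' parameter values and records, for each combination, the growth rate
#' `lambda`, the secondary sex ratio `s2`, and the proportion of mated
#' adults, together with the changes `delta_lambda` and `delta_s2`
#' relative to the matched unharvested baseline (the same parameter
#' combination with `E = 0`). Typical grids sweep the harvest bias
#' `s_h`, harvest rate `E`, divorce rate `d`, and harem size `h`. All
#' runs are deterministic given the integrator settings.
#'
#' @param model A [two_sex_model()] supplying the base parameters.
#' @param grid Named list of parameter values to cross; names must be
#'   model parameters (e.g. `list(d = c(0, 1), s_h = c(0, 0.5, 1))`).
#' @param ... Passed to [equilibrate()] (e.g. `tol`, `t_max`).
#' @return A data frame of class `bmmr_sweep`: one row per grid point
#'   with the swept parameters, `lambda`, `s2`, `prop_mated`,
#'   `delta_lambda`, `delta_s2`, `converged`.
#' @examples
#' m <- two_sex_model(h = 1, k = 20)
#' sw <- harvest_sweep(m, list(d = c(0, 1), E = c(0, 1)))
#' @export
harvest_sweep <- function(model, grid, ...) {
  stopifnot(inherits(model, "bmmr_model"))
  if (!is.list(grid) || is.null(names(grid)) || any(names(grid) == "")) {
    stop("'grid' must be a named list of parameter value vectors")
  }
  bad <- setdiff(names(grid), names(model$params))
  if (length(bad)) {
    stop("unknown parameter(s) in grid: ", paste(bad, collapse = ", "))
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)

  model_at <- function(row) {
    p <- model$params
    p[names(row)] <- as.list(row)
    m <- model
    m$params <- validate_params(p)
    m$space <- stage_space(p$h)
    m
  }

  res <- vector("list", nrow(combos))
  base_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(combos))) {
    row <- combos[r, , drop = FALSE]
    eq <- equilibrate(model_at(row), keep_trajectory = FALSE, ...)
    # matched unharvested baseline: same combination with E = 0
    row0 <- row
    row0$E <- 0
    key <- paste(vapply(setdiff(names(row0), "s_h"),
                        function(nm) format(row0[[nm]], digits = 15), ""),
                 collapse = "\r")
    if (is.null(base_cache[[key]])) {
      base_cache[[key]] <- if (model_at(row)$params$E == 0) {
        c(lambda = eq$lambda, s2 = eq$s2)
      } else {
        eq0 <- equilibrate(model_at(row0), keep_trajectory = FALSE, ...)
        c(lambda = eq0$lambda, s2 = eq0$s2)
      }
    }
    b <- base_cache[[key]]
    res[[r]] <- data.frame(lambda = eq$lambda, s2 = eq$s2,
                           prop_mated = eq$prop_mated,
                           delta_lambda = eq$lambda - b[["lambda"]],
                           delta_s2 = eq$s2 - b[["s2"]],
                           converged = eq$converged)
  }
  out <- cbind(combos, do.call(rbind, res))
  class(out) <- c("bmmr_sweep", "data.frame")
  out
}

#' @export
print.bmmr_sweep <- function(x, ...) {
  cat("Harvest / mating-system sweep:", nrow(x), "parameter combinations\n")
  print.data.frame(x, digits = 5, row.names = FALSE, ...)
  invisible(x)
}

#' Plot a sweep result
#'
#' Line plot of an outcome column against one swept parameter, with one
#' line per level of an optional grouping parameter.
#'
#' @param x A `bmmr_sweep`.
#' @param xvar Name of the swept parameter for the x axis.
#' @param yvar Outcome column (`"lambda"`, `"s2"`, `"prop_mated"`,
#'   `"delta_lambda"`, `"delta_s2"`).
#' @param by Optional name of a second swept parameter; one line per
#'   value.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bmmr_sweep <- function(x, xvar, yvar = "lambda", by = NULL, ...) {
  stopifnot(xvar %in% names(x), yvar %in% names(x))
  if (is.null(by)) {
    ord <- order(x[[xvar]])
    graphics::plot(x[[xvar]][ord], x[[yvar]][ord], type = "b",
                   xlab = xvar, ylab = yvar, ...)
  } else {
    stopifnot(by %in% names(x))
    levels_by <- sort(unique(x[[by]]))
    xs <- sort(unique(x[[xvar]]))
    ymat <- sapply(levels_by, function(g) {
      sub <- x[x[[by]] == g, ]
      sub[[yvar]][match(xs, sub[[xvar]])]
    })
    graphics::matplot(xs, ymat, type = "b", pch = 1, lty = 1,
                      xlab = xvar, ylab = yvar, ...)
    graphics::legend("topright", legend = paste(by, "=", levels_by),
                     col = seq_along(levels_by), lty = 1, bty = "n")
  }
  invisible(x)
}
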