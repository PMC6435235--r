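#' Construct a two-sex stage-structured model
#'
#' Defines a continuous-time two-sex population model in which the life
#' cycle is decomposed into three simultaneous processes — union
#' formation (mating), birth, and transitions (mortality, maturation,
#' divorce) — each described by a rate matrix. Their average is the
#' projection matrix `A = (T + B + U)/3` driving `dn/dt = A[n] n`.
#' The model covers monogamy (`h = 1`, unions are pairs) and polygyny
#' (`h > 1`, unions are harems of one male and up to `h` females, formed
#' at full size and shrinking by female death or departure).
#'
#' All rates are per unit time. Harvest adds `E * s_h` to adult male
#' mortality and `E * (1 - s_h)` to adult female mortality (only adults
#' are harvested); use [apply_harvest()] to fold harvest into the
#' mortality rates before building matrices.
#'
#' @param h Maximum harem size; integer `>= 1` (`1` = monogamy).
#' @param mu_m1,mu_f1 Juvenile male / female mortality rates.
#' @param mu_m2,mu_f2 Adult male / female mortality rates.
#' @param alpha_m,alpha_f Male / female maturation rates.
#' @param d Divorce rate: rate at which a pair bond breaks, or at which
#'   a female departs her harem.
#' @param k Per-female reproductive rate within a union; a harem of `i`
#'   females produces offspring at total rate `i * k`.
#' @param s1 Primary sex ratio: proportion of offspring born male.
#' @param E Total adult harvest rate, `>= 0`.
#' @param s_h Harvested sex ratio: proportion of harvest targeting
#'   males, in `[0, 1]`.
#' @param mating A [mating_spec()]; defaults to the harmonic mean.
#'
#' @return An object of class `bmmr_model`: a list with the validated
#'   parameters (`params`), the [stage_space()] (`space`), and the
#'   mating specification (`mating`).
#'
#' @seealso [equilibrate()] to find the stable stage distribution and
#'   growth rate; [process_matrices()] for the U, B, T, A matrices;
#'   [harvest_sweep()] for parameter sweeps.
#' @examples
#' m <- two_sex_model(h = 1, mu_m1 = 0.5, mu_f1 = 0.5, mu_m2 = 0.1,
#'                    mu_f2 = 0.1, alpha_m = 0.5, alpha_f = 0.5,
#'                    d = 0.1, k = 20, s1 = 0.5)
#' m
#' @export
two_sex_model <- function(h = 1, mu_m1 = 0.5, mu_f1 = 0.5, mu_m2 = 0.1,
                          mu_f2 = 0.1, alpha_m = 0.5, alpha_f = 0.5,
                          d = 0.1, k = 20, s1 = 0.5, E = 0, s_h = 0.5,
                          mating = mating_spec("harmonic")) {
  params <- list(h = h, mu_m1 = mu_m1, mu_f1 = mu_f1, mu_m2 = mu_m2,
                 mu_f2 = mu_f2, alpha_m = alpha_m, alpha_f = alpha_f,
                 d = d, k = k, s1 = s1, E = E, s_h = s_h)
  validate_params(params)
  if (!inherits(mating, "mating_spec")) {
    stop("'mating' must be a mating_spec object")
  }
  structure(
    list(params = params, space = stage_space(h), mating = mating),
    class = "bmmr_model"
  )
}

validate_params <- function(p) {
  rates <- c("mu_m1", "mu_f1", "mu_m2", "mu_f2", "alpha_m", "alpha_f",
             "d", "k", "E")
  for (nm in rates) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop("parameter '", nm, "' must be a single nonnegative number")
    }
  }
  for (nm in c("s1", "s_h")) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("parameter '", nm, "' must be a single number in [0, 1]")
    }
  }
  if (length(p$h) != 1L || !is.finite(p$h) || p$h < 1 ||
      p$h != round(p$h)) {
    stop("parameter 'h' must be a single integer >= 1")
  }
  invisible(p)
}

#' Fold harvest into the adult mortality rates
#'
#' Applies the harvest schedule to the model: adult male mortality
#' becomes `mu_m2 + E * s_h` and adult female mortality
#' `mu_f2 + E * (1 - s_h)`; juvenile rates are untouched (only adults
#' are harvested). The returned model has `E = 0` so that harvest is
#' not applied twice.
#'
#' @param model A [two_sex_model()].
#' @return A `bmmr_model` with harvested adult mortalities and `E = 0`.
#' @examples
#' m <- two_sex_model(E = 1, s_h = 1, mu_m2 = 0.1)
#' apply_harvest(m)$params$mu_m2  # 1.1
#' @export
apply_harvest <- function(model) {
  stopifnot(inherits(model, "bmmr_model"))
  p <- model$params
  if (p$E == 0) return(model)
  p$mu_m2 <- p$mu_m2 + p$E * p$s_h
  p$mu_f2 <- p$mu_f2 + p$E * (1 - p$s_h)
  p$E <- 0
  model$params <- p
  model
}

#' @export
print.bmmr_model <- function(x, ...) {
  p <- x$params
  cat("Two-sex stage-structured model (continuous time)\n")
  cat("  mating system: ",
      if (p$h == 1) "monogamy (h = 1)" else
        sprintf("polygyny (max harem size h = %d)", p$h),
      ", divorce rate d = ", p$d, "\n", sep = "")
  cat(sprintf("  mortality: juveniles (%g, %g), adults (%g, %g) [male, female]\n",
              p$mu_m1, p$mu_f1, p$mu_m2, p$mu_f2))
  cat(sprintf("  maturation: (%g, %g); births: k = %g per female, s1 = %g\n",
              p$alpha_m, p$alpha_f, p$k, p$s1))
  if (p$E > 0) {
    cat(sprintf("  harvest: E = %g, fraction on males s_h = %g\n", p$E, p$s_h))
  } else {
    cat("  harvest: none\n")
  }
  print(x$mating)
  invisible(x)
}

#' @export
coef.bmmr_model <- function(object, ...) {
  unlist(object$params)
}
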