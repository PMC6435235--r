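#' Mating function specification
#'
#' The rate at which single adult males and females form reproductive
#' unions is modelled by a mating (marriage) function `M(m, f)` from the
#' generalized weighted mean (Holder mean) family
#' \deqn{M = c\,[\beta f^{\alpha} + (1-\beta) m^{\alpha}]^{1/\alpha}}
#' with female weight `beta` in `[0, 1]`, exponent `alpha < 0`, and scale
#' `c > 0`. Members of this family are degree-1 homogeneous and vanish
#' when either sex is absent, the two biological requirements for a
#' two-sex birth function. Named members:
#'
#' * `"harmonic"`: `M = 2mf/(m + f)` — the Holder mean at
#'   `beta = 1/2`, `alpha = -1`; the default used in all worked models.
#' * `"geometric"`: `M = f^beta m^(1-beta)` — the `alpha -> 0` limit.
#' * `"minimum"`: `M = min(m, f)` — the `alpha -> -Inf` limit.
#' * `"generalized"`: the family itself, with `beta`, `alpha`, `scale`
#'   free.
#'
#' @param family One of `"harmonic"`, `"geometric"`, `"minimum"`,
#'   `"generalized"`.
#' @param beta Weight on females, in `[0, 1]`. Fixed at `1/2` for the
#'   named families.
#' @param alpha Holder exponent, `< 0`; only used by `"generalized"`.
#' @param scale Positive scale multiplier on the mean; default 1 (under
#'   which `generalized(beta = 1/2, alpha = -1)` coincides exactly with
#'   `"harmonic"`).
#'
#' @return An object of class `mating_spec`.
#' @examples
#' mating_spec()                       # harmonic mean
#' mating_spec("generalized", beta = 0.5, alpha = -1)  # identical rates
#' @export
mating_spec <- function(family = c("harmonic", "geometric", "minimum",
                                   "generalized"),
                        beta = 0.5, alpha = -1, scale = 1) {
  family <- match.arg(family)
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 1) {
    stop("'beta' must be a single number in [0, 1]")
  }
  if (family == "generalized" &&
      (length(alpha) != 1L || !is.finite(alpha) || alpha >= 0)) {
    stop("'alpha' must be a single negative number for the generalized family")
  }
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("'scale' must be a single positive number")
  }
  if (family != "generalized") beta <- 0.5
  structure(list(family = family, beta = beta, alpha = alpha, scale = scale),
            class = "mating_spec")
}

#' @export
print.mating_spec <- function(x, ...) {
  cat("Mating function:", x$family)
  if (x$family == "generalized") {
    cat(sprintf(" (beta = %g, alpha = %g, scale = %g)", x$beta, x$alpha,
                x$scale))
  }
  cat("\n")
  invisible(x)
}

check_mf <- function(m, f) {
  if (length(m) != 1L || length(f) != 1L || any(!is.finite(c(m, f))) ||
      m < 0 || f < 0) {
    stop("male and female densities must be single finite nonnegative numbers")
  }
}

#' Total mating rate
#'
#' Evaluates the total mating function `M(m, f)`: unions formed per unit
#' time given densities `m` of available males and `f` of available
#' females. Degree-1 homogeneous in `(m, f)`; zero whenever either sex
#' is absent.
#'
#' @param spec A [mating_spec()].
#' @param m,f Nonnegative available male / female densities.
#' @return Union formation rate `M >= 0`.
#' @examples
#' mating_rate(mating_spec(), 1, 3)  # 2*1*3/(1+3) = 1.5
#' @export
mating_rate <- function(spec, m, f) {
  stopifnot(inherits(spec, "mating_spec"))
  check_mf(m, f)
  m <- unname(m); f <- unname(f)
  if (m == 0 || f == 0) return(0)
  b <- spec$beta
  M <- switch(spec$family,
    harmonic = {
      # beta-weighted harmonic mean; b = 1/2 gives 2mf/(m+f)
      1 / (b / f + (1 - b) / m)
    },
    geometric = f^b * m^(1 - b),
    minimum = min(m, f),
    generalized = (b * f^spec$alpha + (1 - b) * m^spec$alpha)^(1 / spec$alpha)
  )
  spec$scale * M
}

#' Per-capita mating rates
#'
#' Converts the total mating rate into per-capita rates `U_m = M/m`
#' (per available male) and `U_f = M/f` (per available female), taking
#' the finite algebraic limit when the own-sex density is zero so the
#' rates stay defined on the boundary (the limit multiplies a zero
#' density, so no flux results). Both are zero when `m + f = 0`.
#' Degree-0 homogeneous in `(m, f)`.
#'
#' @inheritParams mating_rate
#' @return Named numeric vector `c(U_m = , U_f = )`.
#' @examples
#' per_capita_rates(mating_spec(), 1, 3)  # U_m = 1.5, U_f = 0.5
#' @export
per_capita_rates <- function(spec, m, f) {
  stopifnot(inherits(spec, "mating_spec"))
  check_mf(m, f)
  m <- unname(m); f <- unname(f)
  b <- spec$beta
  # own-sex -> 0 limits of M/own (0 used where the limit diverges or the
  # other sex is also absent; the rate then multiplies a zero density)
  lim_m <- switch(spec$family,
    harmonic    = 1 / (1 - b),          # f / ((1-b) f)
    geometric   = 0,                    # (f/m)^b diverges
    minimum     = 1,
    generalized = (1 - b)^(1 / spec$alpha)
  )
  lim_f <- switch(spec$family,
    harmonic    = 1 / b,
    geometric   = 0,
    minimum     = 1,
    generalized = b^(1 / spec$alpha)
  )
  U_m <- if (m > 0) mating_rate(spec, m, f) / m
         else if (f > 0) spec$scale * lim_m else 0
  U_f <- if (f > 0) mating_rate(spec, m, f) / f
         else if (m > 0) spec$scale * lim_f else 0
  c(U_m = U_m, U_f = U_f)
}

#' Polygynous mating rates with prospective harems
#'
#' In the polygynous model new unions always form at the maximum harem
#' size `h`, so the quantity a male competes for is a *prospective
#' harem*: `f2 / h` single females. The total mating rate is the mating
#' function evaluated at `(m2, f2/h)`; per-capita rates follow as
#' `U_m = M/m2`, `U_f = M/f2`. For the harmonic family this gives
#' `M = 2 m2 f2 / (h m2 + f2)`, `U_m = 2 f2 / (h m2 + f2)`,
#' `U_f = 2 m2 / (h m2 + f2)`; `h = 1` recovers the monogamous rates.
#'
#' @inheritParams mating_rate
#' @param m2,f2 Single adult male / female densities.
#' @param h Maximum harem size, integer `>= 1`.
#' @return Named numeric vector `c(M = , U_m = , U_f = )`.
#' @examples
#' polygynous_rates(mating_spec(), m2 = 1, f2 = 3, h = 3)  # M = 1
#' @export
polygynous_rates <- function(spec, m2, f2, h) {
  stopifnot(inherits(spec, "mating_spec"))
  check_mf(m2, f2)
  if (length(h) != 1L || h < 1 || h != round(h)) {
    stop("'h' must be a single integer >= 1")
  }
  m2 <- unname(m2); f2 <- unname(f2)
  M <- mating_rate(spec, m = m2, f = f2 / h)
  U <- per_capita_rates(spec, m = m2, f = f2 / h)
  # U_f is per prospective harem; per female it is (M / (f2/h)) / h = M/f2
  c(M = M, U_m = unname(U["U_m"]), U_f = unname(U["U_f"]) / h)
}
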