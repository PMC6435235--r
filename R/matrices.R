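#' Union formation rate matrix
#'
#' Builds the union formation matrix `U` at population composition `n`.
#' New unions always form at the maximum size `h`: single adult males
#' leave `m2` at per-capita rate `U_m`, single females leave `f2` at
#' `h * U_f` (each new union absorbs `h` females), and the largest union
#' stage gains `U_m/2` from the `m2` column and `U_f/2` from the `f2`
#' column — halved so the union formed jointly by a male and his females
#' is not counted once per partner. `U` is degree-0 homogeneous in `n`.
#'
#' @param model A [two_sex_model()].
#' @param n Nonnegative stage-density (or frequency) vector, length
#'   `4 + h` in stage order.
#' @return The `s x s` matrix `U`, with stage labels on both dimensions.
#' @export
union_matrix <- function(model, n) {
  sp <- model$space
  check_state(sp, n)
  h <- model$params$h
  r <- polygynous_rates(model$mating, m2 = n[.idx$m2], f2 = n[.idx$f2], h = h)
  U <- matrix(0, sp$s, sp$s, dimnames = list(sp$labels, sp$labels))
  U[.idx$m2, .idx$m2] <- -r[["U_m"]]
  U[.idx$f2, .idx$f2] <- -h * r[["U_f"]]
  U[union_index(sp, h), .idx$m2] <- r[["U_m"]] / 2
  U[union_index(sp, h), .idx$f2] <- r[["U_f"]] / 2
  U
}

#' Birth rate matrix
#'
#' Births flow from union stages to the juvenile stages: a union with a
#' harem of `i` females reproduces at total rate `i * k`, split
#' `s1 : (1 - s1)` between male and female offspring. `B` does not
#' depend on the population composition.
#'
#' @inheritParams union_matrix
#' @return The `s x s` matrix `B`.
#' @export
birth_matrix <- function(model) {
  sp <- model$space
  p <- model$params
  B <- matrix(0, sp$s, sp$s, dimnames = list(sp$labels, sp$labels))
  i <- seq_len(p$h)
  B[.idx$m1, union_index(sp, i)] <- i * p$k * p$s1
  B[.idx$f1, union_index(sp, i)] <- i * p$k * (1 - p$s1)
  B
}

#' Transition rate matrix
#'
#' Mortality, maturation, and union dissolution. Juveniles mature at
#' rate `alpha_m` / `alpha_f` and die at `mu_m1` / `mu_f1`; single
#' adults die at `mu_m2` / `mu_f2`. A union `u_i` changes in three
#' ways: the male leader dies (rate `mu_m2`), dissolving the union and
#' returning `i` females to `f2`; a female member dies (rate `mu_f2`),
#' shrinking `u_i` to `u_{i-1}`; or a female departs (divorce rate `d`),
#' returning one female to `f2` and shrinking the union. For `u_1` the
#' shrunken union is a single male, so female death or departure also
#' returns the male to `m2`.
#'
#' @param model A [two_sex_model()].
#' @param per_individual_female_mortality Extension flag (default
#'   `FALSE`): if `TRUE`, the female death rate inside `u_i` scales with
#'   harem size as `i * mu_f2` instead of one female death event per
#'   union per unit time. The default reproduces the canonical model.
#' @return The `s x s` matrix `T`.
#' @export
transition_matrix <- function(model, per_individual_female_mortality = FALSE) {
  sp <- model$space
  p <- model$params
  Tm <- matrix(0, sp$s, sp$s, dimnames = list(sp$labels, sp$labels))
  Tm[.idx$m1, .idx$m1] <- -(p$mu_m1 + p$alpha_m)
  Tm[.idx$m2, .idx$m1] <- p$alpha_m
  Tm[.idx$f1, .idx$f1] <- -(p$mu_f1 + p$alpha_f)
  Tm[.idx$f2, .idx$f1] <- p$alpha_f
  Tm[.idx$m2, .idx$m2] <- -p$mu_m2
  Tm[.idx$f2, .idx$f2] <- -p$mu_f2
  for (i in seq_len(p$h)) {
    j <- union_index(sp, i)
    mu_f <- if (per_individual_female_mortality) i * p$mu_f2 else p$mu_f2
    Tm[j, j] <- -(p$mu_m2 + mu_f + p$d)
    # male leader dies: i females back to f2; female loss: shrink by one
    Tm[.idx$f2, j] <- i * p$mu_m2 + p$d
    if (i == 1L) {
      Tm[.idx$m2, j] <- mu_f + p$d
    } else {
      Tm[j - 1L, j] <- mu_f + p$d
    }
  }
  Tm
}

#' Projection matrix and process matrices
#'
#' `projection_matrix()` assembles `A = (T + B + U[n]) / 3`, the average
#' of the three simultaneous process rate matrices; `process_matrices()`
#' returns all four. `A` inherits degree-0 homogeneity in `n` from the
#' per-capita mating rates, so the dynamics are frequency-dependent and
#' `A` may be evaluated at a frequency vector `p` as well as a density
#' vector `n`. Harvest is not applied here; pass the model through
#' [apply_harvest()] first if `E > 0`.
#'
#' @inheritParams union_matrix
#' @return `projection_matrix()`: the `s x s` matrix `A`.
#'   `process_matrices()`: a list with elements `U`, `B`, `T`, `A`.
#' @examples
#' m <- two_sex_model(h = 1, d = 0.1)
#' A <- projection_matrix(m, rep(1, 5))
#' @export
projection_matrix <- function(model, n) {
  (transition_matrix(model) + birth_matrix(model) + union_matrix(model, n)) / 3
}

#' @rdname projection_matrix
#' @export
process_matrices <- function(model, n) {
  U <- union_matrix(model, n)
  B <- birth_matrix(model)
  Tm <- transition_matrix(model)
  list(U = U, B = B, T = Tm, A = (U + B + Tm) / 3)
}
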