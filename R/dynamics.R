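#' Right-hand sides of the density and frequency dynamics
#'
#' `density_rhs()` evaluates `dn/dt = A[n] n` for the stage densities.
#' `frequency_rhs()` evaluates the induced dynamics of the stage
#' frequency vector `p = n / ||n||_1` on the simplex,
#' `dp/dt = (I - p 1') A[p] p`, whose components sum to zero; its
#' equilibria are the stable stage distributions.
#'
#' @param model A [two_sex_model()] (harvest is folded in via
#'   [apply_harvest()] before evaluation).
#' @param n Nonnegative stage-density vector.
#' @param p Stage-frequency vector: nonnegative, summing to 1 within
#'   `simplex_tol`.
#' @param simplex_tol Tolerance on `|sum(p) - 1|`.
#' @return The derivative vector, same length as the state.
#' @export
density_rhs <- function(model, n) {
  model <- apply_harvest(model)
  check_state(model$space, n)
  as.numeric(projection_matrix(model, n) %*% n)
}

#' @rdname density_rhs
#' @export
frequency_rhs <- function(model, p, simplex_tol = 1e-6) {
  model <- apply_harvest(model)
  check_state(model$space, p, what = "p")
  if (abs(sum(p) - 1) > simplex_tol) {
    stop("'p' must lie on the simplex: sum(p) = ", format(sum(p)))
  }
  Ap <- as.numeric(projection_matrix(model, p) %*% p)
  Ap - p * sum(Ap)
}

#' Equilibrium stage structure and long-term growth rate
#'
#' Integrates the frequency dynamics `dp/dt = (I - p 1') A[p] p` from
#' `p0` with an adaptive Runge-Kutta (4/5) solver until the stage
#' frequencies converge, then extracts the long-term (Malthusian)
#' growth rate `lambda` as the dominant eigenvalue — largest real part —
#' of `A` evaluated at the equilibrium `p_hat`, together with the
#' associated right eigenvector `w` (the stable stage distribution,
#' which coincides with `p_hat`).
#'
#' Convergence is declared when, across a checkpoint window of
#' `checkpoint` time units, both the max-norm change in `p` and the
#' max-norm of `dp/dt` fall below `tol`. At checkpoints, negative
#' round-off frequencies are clipped to zero and `p` is renormalized to
#' the simplex; the right-hand side itself is never altered. If the
#' dual criterion is not met by `t_max` the result is returned with
#' `converged = FALSE` and the residual reported, not an error.
#'
#' @param model A [two_sex_model()]; harvest (`E > 0`) is applied
#'   automatically.
#' @param p0 Initial frequency vector; default uniform over stages.
#' @param tol Convergence tolerance (both criteria).
#' @param t_max Maximum integration time.
#' @param checkpoint Checkpoint window length (time units).
#' @param rtol,atol Relative / absolute integrator tolerances. `rtol`
#'   must be well below `tol` for the residual criterion to be
#'   reachable.
#' @param keep_trajectory Record the frequency trajectory at solver
#'   steps (for plotting convergence)? Default `TRUE`.
#'
#' @return An object of class `bmmr_equilibrium` with elements
#'   `p_hat` (equilibrium frequencies, named by stage), `lambda`,
#'   `w` (dominant right eigenvector, normalized to sum 1),
#'   `converged`, `residual` (max-norm of `dp/dt` at `p_hat`),
#'   `t_final`, `trajectory` (data frame: `t`, one column per stage),
#'   `s2` (secondary sex ratio), `prop_mated`, and the (harvested)
#'   `model`.
#'
#' @examples
#' m <- two_sex_model(h = 1, d = 0.1)
#' eq <- equilibrate(m)
#' eq$lambda
#' eq$s2        # 0.5: symmetric vital rates, no harvest
#' @export
equilibrate <- function(model, p0 = NULL, tol = 1e-10, t_max = 1e4,
                        checkpoint = 10, rtol = 1e-10, atol = 1e-12,
                        keep_trajectory = TRUE) {
  stopifnot(inherits(model, "bmmr_model"))
  model <- apply_harvest(model)
  sp <- model$space
  if (is.null(p0)) {
    p0 <- rep(1 / sp$s, sp$s)
  } else {
    check_state(sp, p0, what = "p0")
    if (abs(sum(p0) - 1) > 1e-6) stop("'p0' must sum to 1")
    p0 <- p0 / sum(p0)
  }
  if (tol <= 0) stop("'tol' must be positive")

  Tm <- transition_matrix(model)
  B <- birth_matrix(model)
  rhs <- function(t, p, parms) {
    A <- (Tm + B + union_matrix(model, pmax(p, 0))) / 3
    Ap <- as.numeric(A %*% p)
    list(Ap - p * sum(Ap))
  }

  p <- p0
  t0 <- 0
  converged <- FALSE
  traj <- if (keep_trajectory) list(c(0, p0)) else NULL
  repeat {
    sol <- deSolve::ode(y = p, times = c(t0, t0 + checkpoint), func = rhs,
                        parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    if (keep_trajectory) {
      traj[[length(traj) + 1L]] <- sol[nrow(sol), ]
    }
    p_new <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    p_new <- p_new / sum(p_new)
    dp <- rhs(0, p_new, NULL)[[1]]
    t0 <- t0 + checkpoint
    if (max(abs(p_new - p)) < tol && max(abs(dp)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
    if (t0 >= t_max) break
  }

  eig <- growth_rate_and_structure(model, p)
  names(p) <- sp$labels
  trajectory <- NULL
  if (keep_trajectory) {
    trajectory <- as.data.frame(do.call(rbind, traj))
    names(trajectory) <- c("t", sp$labels)
  }
  structure(
    list(
      p_hat = p,
      lambda = eig$lambda,
      w = eig$w,
      converged = converged,
      residual = max(abs(rhs(0, p, NULL)[[1]])),
      t_final = t0,
      trajectory = trajectory,
      s2 = secondary_sex_ratio(sp, p),
      prop_mated = proportion_mated(sp, p),
      model = model
    ),
    class = "bmmr_equilibrium"
  )
}

#' Growth rate and stable structure from the projection matrix
#'
#' At a candidate equilibrium composition `p_hat`, the long-term growth
#' rate is the eigenvalue of `A[p_hat]` with the largest real part (the
#' continuous-time, Malthusian convention: densities grow like
#' `exp(lambda t)`); for matrices with nonnegative off-diagonals this
#' eigenvalue is real. The associated right eigenvector, rescaled to be
#' nonnegative with unit sum, is the stable stage distribution.
#'
#' @param model A [two_sex_model()].
#' @param p_hat Frequency vector at which to evaluate `A`.
#' @param tol Tolerance for the dominance / realness diagnostics.
#' @return List with `lambda` (real scalar) and `w` (named, sums to 1).
#' @export
growth_rate_and_structure <- function(model, p_hat, tol = 1e-8) {
  model <- apply_harvest(model)
  sp <- model$space
  check_state(sp, p_hat, what = "p_hat")
  A <- projection_matrix(model, p_hat)
  eig <- eigen(A)
  i <- which.max(Re(eig$values))
  lam <- eig$values[i]
  if (abs(Im(lam)) > tol * max(1, abs(Re(lam)))) {
    stop("dominant eigenvalue has nontrivial imaginary part: ",
         format(lam))
  }
  w <- eig$vectors[, i]
  if (max(abs(Im(w))) > tol * max(abs(Re(w)))) {
    stop("dominant eigenvector is not real within tolerance")
  }
  w <- Re(w)
  if (sum(w) < 0) w <- -w
  if (any(w < -tol * max(abs(w)))) {
    stop("dominant eigenvector has mixed signs; dominance is ambiguous")
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  names(w) <- sp$labels
  list(lambda = Re(lam), w = w)
}

#' Simulate the stage-density dynamics
#'
#' Integrates `dn/dt = A[n] n` directly (densities, not frequencies),
#' e.g. to display exponential growth or to cross-check the growth rate
#' against the eigenvalue route via the late-time slope of
#' `log ||n(t)||_1`.
#'
#' @param object A [two_sex_model()].
#' @param nsim,seed Ignored (the dynamics are deterministic); present
#'   for compatibility with [stats::simulate()].
#' @param n0 Initial density vector; default: one individual per stage.
#' @param times Output time points.
#' @param rtol,atol Integrator tolerances.
#' @param ... Unused.
#' @return A data frame: `t`, one column per stage, and `total` (the
#'   1-norm of `n`).
#' @examples
#' m <- two_sex_model(h = 1, d = 0.1)
#' tr <- simulate(m, times = seq(0, 20, 0.5))
#' @export
simulate.bmmr_model <- function(object, nsim = 1, seed = NULL, n0 = NULL,
                                times = seq(0, 50, by = 0.5),
                                rtol = 1e-10, atol = 1e-12, ...) {
  model <- apply_harvest(object)
  sp <- model$space
  if (is.null(n0)) n0 <- rep(1, sp$s)
  check_state(sp, n0, what = "n0")
  Tm <- transition_matrix(model)
  B <- birth_matrix(model)
  rhs <- function(t, n, parms) {
    A <- (Tm + B + union_matrix(model, pmax(n, 0))) / 3
    list(as.numeric(A %*% n))
  }
  sol <- deSolve::ode(y = n0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("t", sp$labels)
  out$total <- rowSums(out[, sp$labels, drop = FALSE])
  out
}
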