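#' @export
print.bmmr_equilibrium <- function(x, ...) {
  cat("Equilibrium of two-sex frequency dynamics\n")
  cat(sprintf("  converged: %s (t = %g, residual %.2e)\n",
              x$converged, x$t_final, x$residual))
  cat(sprintf("  growth rate lambda = %.6f\n", x$lambda))
  cat(sprintf("  secondary sex ratio s2 = %.6f; proportion mated = %.6f\n",
              x$s2, x$prop_mated))
  cat("  stable stage distribution:\n")
  print(round(x$p_hat, 6))
  invisible(x)
}

#' @export
summary.bmmr_equilibrium <- function(object, ...) {
  structure(list(eq = object), class = "summary.bmmr_equilibrium")
}

#' @export
print.summary.bmmr_equilibrium <- function(x, ...) {
  eq <- x$eq
  print(eq$model)
  print(eq)
  cat("  eigenvector check: max |w - p_hat| =",
      format(max(abs(eq$w - eq$p_hat)), digits = 3), "\n")
  invisible(x)
}

#' Scalar population properties of an equilibrium
#'
#' @param object A `bmmr_equilibrium` from [equilibrate()].
#' @param ... Unused.
#' @return Named vector: `lambda`, `s2`, `prop_mated`.
#' @export
coef.bmmr_equilibrium <- function(object, ...) {
  c(lambda = object$lambda, s2 = object$s2, prop_mated = object$prop_mated)
}

#' Equilibrium defect of a converged structure
#'
#' Residuals of the eigen-equation at the equilibrium:
#' `A[p_hat] p_hat - lambda p_hat`, which should be numerically zero at
#' a converged stable stage distribution.
#'
#' @param object A `bmmr_equilibrium`.
#' @param ... Unused.
#' @return Named numeric vector, one entry per stage.
#' @export
residuals.bmmr_equilibrium <- function(object, ...) {
  A <- projection_matrix(object$model, object$p_hat)
  r <- as.numeric(A %*% object$p_hat) - object$lambda * object$p_hat
  names(r) <- object$model$space$labels
  r
}

#' Plot convergence of the stage frequencies
#'
#' One line per stage frequency against time, ending at the stable
#' stage distribution.
#'
#' @param x A `bmmr_equilibrium` (run with `keep_trajectory = TRUE`).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bmmr_equilibrium <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("no trajectory recorded; rerun equilibrate() with keep_trajectory = TRUE")
  }
  tr <- x$trajectory
  stages <- setdiff(names(tr), "t")
  graphics::matplot(tr$t, as.matrix(tr[stages]), type = "l", lty = 1,
                    xlab = "time", ylab = "stage frequency", ...)
  graphics::legend("topright", legend = stages,
                   col = seq_along(stages), lty = 1, bty = "n")
  invisible(x)
}
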