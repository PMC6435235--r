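#' Stage space for a two-sex population with unions
#'
#' Constructs the ordered stage structure used throughout the package:
#' juvenile males (`m1`), single adult males (`m2`), juvenile females
#' (`f1`), single adult females (`f2`), followed by the union stages.
#' For maximum harem size `h` there are `h` union stages `u1, ..., uh`,
#' where `ui` is one adult male with a harem of `i` females; for
#' `h = 1` the single union stage is labelled `u` (a monogamous pair).
#'
#' Each stage carries accounting weights: `multiplicity` (individuals per
#' unit of the stage), `adult_males` and `adult_females` (adult content
#' per unit of the stage). These weights drive conservation checks, the
#' secondary sex ratio, and the proportion of mated adults.
#'
#' @param h Maximum harem size; integer `>= 1`. `h = 1` is monogamy.
#'
#' @return An object of class `stage_space`: a list with elements
#'   `h`, `s` (stage count, `4 + h`), `labels`, `multiplicity`,
#'   `adult_males`, `adult_females`.
#'
#' @examples
#' stage_space(1)   # 5 stages: m1 m2 f1 f2 u
#' stage_space(3)   # 7 stages: m1 m2 f1 f2 u1 u2 u3
#' @export
stage_space <- function(h) {
  if (length(h) != 1L || !is.numeric(h) || is.na(h) || h < 1 ||
      h != round(h)) {
    stop("'h' must be a single integer >= 1 (maximum harem size), got: ",
         deparse(substitute(h)), " = ", paste(h, collapse = ", "))
  }
  h <- as.integer(h)
  union_labels <- if (h == 1L) "u" else paste0("u", seq_len(h))
  labels <- c("m1", "m2", "f1", "f2", union_labels)
  structure(
    list(
      h = h,
      s = 4L + h,
      labels = labels,
      multiplicity = c(1L, 1L, 1L, 1L, 1L + seq_len(h)),
      adult_males = c(0L, 1L, 0L, 0L, rep(1L, h)),
      adult_females = c(0L, 0L, 0L, 1L, seq_len(h))
    ),
    class = "stage_space"
  )
}

#' @export
print.stage_space <- function(x, ...) {
  cat("Two-sex stage space, maximum harem size h =", x$h,
      "(", x$s, "stages )\n")
  tab <- data.frame(
    stage = x$labels,
    individuals = x$multiplicity,
    adult_males = x$adult_males,
    adult_females = x$adult_females
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

# index helpers used by the matrix builders; stage order is fixed
.idx <- list(m1 = 1L, m2 = 2L, f1 = 3L, f2 = 4L)

union_index <- function(space, i) 4L + i

check_state <- function(space, n, what = "n") {
  if (length(n) != space$s) {
    stop("'", what, "' must have length ", space$s,
         " (one entry per stage), got ", length(n))
  }
  if (any(!is.finite(n))) stop("'", what, "' contains non-finite entries")
  if (any(n < 0)) stop("'", what, "' must be nonnegative entrywise")
  invisible(n)
}
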