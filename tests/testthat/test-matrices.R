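# Conservation accounting: contracting a process matrix with the
# individuals-per-stage weights isolates the flux of individuals each
# process creates or destroys.
indiv_flux <- function(model, M, n) {
  sum(model$space$multiplicity * as.numeric(M %*% n))
}

test_that("monogamous process matrices match their printed 5x5 forms", {
  m <- baseline_model(h = 1, d = 0.1)
  p <- m$params
  n <- c(0.3, 0.2, 0.25, 0.15, 0.1)
  Um <- 2 * n[4] / (n[2] + n[4])
  Uf <- 2 * n[2] / (n[2] + n[4])
  U_expected <- rbind(
    c(0, 0, 0, 0, 0),
    c(0, -Um, 0, 0, 0),
    c(0, 0, 0, 0, 0),
    c(0, 0, 0, -Uf, 0),
    c(0, Um / 2, 0, Uf / 2, 0))
  expect_equal(unname(union_matrix(m, n)), U_expected, tolerance = 1e-14)

  B_expected <- matrix(0, 5, 5)
  B_expected[1, 5] <- p$k * p$s1        # 10 at k = 20, s1 = 0.5
  B_expected[3, 5] <- p$k * (1 - p$s1)
  expect_equal(unname(birth_matrix(m)), B_expected)
  expect_equal(birth_matrix(m)["m1", "u"], 10)

  T_expected <- rbind(
    c(-(p$mu_m1 + p$alpha_m), 0, 0, 0, 0),
    c(p$alpha_m, -p$mu_m2, 0, 0, p$mu_f2 + p$d),
    c(0, 0, -(p$mu_f1 + p$alpha_f), 0, 0),
    c(0, 0, p$alpha_f, -p$mu_f2, p$mu_m2 + p$d),
    c(0, 0, 0, 0, -(p$mu_m2 + p$mu_f2 + p$d)))
  expect_equal(unname(transition_matrix(m)), T_expected)
})

test_that("h = 3 polygyny matrices match their printed 7x7 forms", {
  m <- two_sex_model(h = 3, mu_m1 = 0.4, mu_f1 = 0.3, mu_m2 = 0.15,
                     mu_f2 = 0.12, alpha_m = 0.6, alpha_f = 0.45,
                     d = 0.7, k = 12, s1 = 0.55)
  p <- m$params
  n <- c(0.1, 0.2, 0.1, 0.3, 0.1, 0.1, 0.1)
  Um <- 2 * n[4] / (3 * n[2] + n[4])
  Uf <- 2 * n[2] / (3 * n[2] + n[4])
  U_expected <- matrix(0, 7, 7)
  U_expected[2, 2] <- -Um
  U_expected[4, 4] <- -3 * Uf
  U_expected[7, 2] <- Um / 2
  U_expected[7, 4] <- Uf / 2
  expect_equal(unname(union_matrix(m, n)), U_expected, tolerance = 1e-14)

  B_expected <- matrix(0, 7, 7)
  B_expected[1, 5:7] <- (1:3) * p$k * p$s1
  B_expected[3, 5:7] <- (1:3) * p$k * (1 - p$s1)
  expect_equal(unname(birth_matrix(m)), B_expected)

  dd <- -(p$mu_m2 + p$mu_f2 + p$d)
  T_expected <- rbind(
    c(-(p$mu_m1 + p$alpha_m), 0, 0, 0, 0, 0, 0),
    c(p$alpha_m, -p$mu_m2, 0, 0, p$mu_f2 + p$d, 0, 0),
    c(0, 0, -(p$mu_f1 + p$alpha_f), 0, 0, 0, 0),
    c(0, 0, p$alpha_f, -p$mu_f2,
      p$mu_m2 + p$d, 2 * p$mu_m2 + p$d, 3 * p$mu_m2 + p$d),
    c(0, 0, 0, 0, dd, p$mu_f2 + p$d, 0),
    c(0, 0, 0, 0, 0, dd, p$mu_f2 + p$d),
    c(0, 0, 0, 0, 0, 0, dd))
  expect_equal(unname(transition_matrix(m)), T_expected)
})

test_that("harvest adds to the adult mortalities only", {
  m0 <- baseline_model(E = 0)
  expect_identical(apply_harvest(m0)$params, m0$params)

  m1 <- baseline_model(E = 1, s_h = 1)
  h1 <- apply_harvest(m1)$params
  expect_equal(h1$mu_m2, 1.1)
  expect_equal(h1$mu_f2, 0.1)
  expect_equal(h1$mu_m1, 0.5)  # juveniles are not harvested
  expect_equal(h1$E, 0)

  h5 <- apply_harvest(baseline_model(E = 1, s_h = 0.5))$params
  expect_equal(h5$mu_m2, 0.6)
  expect_equal(h5$mu_f2, 0.6)
  expect_error(baseline_model(E = -1), "nonnegative")
  expect_error(baseline_model(s_h = 2), "\\[0, 1\\]")
})

test_that("mating, divorce and maturation conserve individuals; deaths and births account exactly", {
  set.seed(101)
  for (h in 1:10) {
    for (rep in 1:3) {
      m <- random_model(h)
      p <- m$params
      sp <- m$space
      n <- runif(sp$s, 0, 2)
      pm <- process_matrices(m, n)
      # union formation moves individuals between stages, never loses any
      expect_lt(abs(indiv_flux(m, pm$U, n)), 1e-12)
      # transitions lose exactly the death flux
      deaths <- p$mu_m1 * n[1] + p$mu_m2 * n[2] + p$mu_f1 * n[3] +
        p$mu_f2 * n[4] + sum((p$mu_m2 + p$mu_f2) * n[-(1:4)])
      expect_equal(indiv_flux(m, pm$T, n), -deaths, tolerance = 1e-12)
      # births add k per female per union unit
      expect_equal(indiv_flux(m, pm$B, n),
                   p$k * sum(seq_len(h) * n[-(1:4)]), tolerance = 1e-12)
      # the assembled matrix has nonnegative off-diagonals
      offdiag <- pm$A - diag(diag(pm$A))
      expect_true(all(offdiag >= -1e-14))
    }
  }
})

test_that("with no deaths, births or divorce the system is closed", {
  m <- two_sex_model(h = 4, mu_m1 = 0, mu_f1 = 0, mu_m2 = 0, mu_f2 = 0,
                     alpha_m = 0.5, alpha_f = 0.3, d = 0, k = 0, s1 = 0.5)
  set.seed(5)
  for (rep in 1:5) {
    n <- runif(8, 0, 3)
    expect_lt(abs(indiv_flux(m, projection_matrix(m, n), n)), 1e-12)
  }
})

test_that("projection matrix is frequency-dependent (degree-0 homogeneous)", {
  set.seed(9)
  m <- baseline_model(h = 3, d = 0.4)
  for (rep in 1:5) {
    n <- runif(7, 0.01, 2)
    c0 <- runif(1, 0.1, 100)
    expect_equal(projection_matrix(m, c0 * n), projection_matrix(m, n),
                 tolerance = 1e-12)
  }
})

test_that("degenerate compositions are handled", {
  m <- baseline_model(h = 2)
  n0 <- c(1, 0, 1, 0, 0.5, 0.5)
  expect_equal(unname(union_matrix(m, n0)), matrix(0, 6, 6))
  zero <- two_sex_model(h = 1, mu_m1 = 0, mu_f1 = 0, mu_m2 = 0, mu_f2 = 0,
                        alpha_m = 0, alpha_f = 0, d = 0, k = 0)
  expect_equal(unname(transition_matrix(zero)), matrix(0, 5, 5))
  expect_error(union_matrix(m, c(1, 2)), "length")
  expect_error(union_matrix(m, c(-1, 1, 1, 1, 1, 1)), "nonnegative")
})
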