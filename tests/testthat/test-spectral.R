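test_that("quantization polynomial is monic of degree N + 1 and solves the 2-state chain", {
  m <- binary_choice_model(6, 0.7, 1.3, 0.9, 1.7)
  co <- quantization_polynomial(m)
  expect_length(co, 8)
  expect_identical(co[8], 1)   # monic, exactly
  # 2-state chain by hand: rows R_0 = d(1), Qt = (b + d) - lambda encoded
  # as x = -lambda; the two roots must be -{0, b0 + d1}
  b0 <- 0.8; d1 <- 1.7
  rec <- three_term_recurrence(P = function(j) if (j == 1) b0 else 0,
                               Qt = function(j) c(b0, d1)[j + 1],
                               R = function(j) d1)
  co2 <- quantization_polynomial(rec, N = 1)
  expect_length(co2, 3)
  roots <- sort(Re(polyroot(co2)))
  expect_equal(roots, sort(-c(0, b0 + d1)), tolerance = 1e-12)
})

test_that("recurrence spectrum matches the dense oracle and contains zero", {
  set.seed(21)
  for (N in c(3, 5, 10)) {
    for (k in 1:5) {
      r4 <- runif(4, 0.1, 2)
      m <- binary_choice_model(N, r4[1], r4[2], r4[3], r4[4])
      lam <- suppressWarnings(as.numeric(eigen_spectrum(m)))
      expect_identical(lam[1], 0)
      expect_lt(max(abs(lam - dense_spectrum_oracle(generator(m)))), 1e-6)
    }
  }
})

test_that("dense oracle: 2x2 case, scaling linearity, real spectrum", {
  g <- birth_death_generator(c(0.8, 0), c(0, 1.7))
  expect_equal(dense_spectrum_oracle(g), c(0, 0.8 + 1.7), tolerance = 1e-14)
  g1 <- fixture_birth_death(33, 12)
  lam1 <- dense_spectrum_oracle(g1)
  g3 <- birth_death_generator(3 * g1$birth, 3 * g1$death)
  expect_equal(dense_spectrum_oracle(g3), 3 * lam1, tolerance = 1e-10)
  expect_true(all(lam1 >= -1e-12))
})

test_that("series eigenvectors solve the eigenproblem in the probability basis", {
  m <- binary_choice_model(8, 0.7, 1.3, 0.9, 1.7)
  A <- as.matrix(generator(m))
  lam <- as.numeric(eigen_spectrum(m))
  v0 <- eigenvectors_from_series(m, lam[1])
  expect_equal(v0, stationary_distribution(generator(m)), tolerance = 1e-8)
  for (i in c(2, 4, 8)) {
    v <- eigenvectors_from_series(m, lam[i])
    expect_lt(abs(sum(v)), 1e-8)                       # decaying modes sum to 0
    expect_lt(max(abs(A %*% v + lam[i] * v)), 1e-8)    # A C = -lambda C
  }
  mv <- vacillating_voter_model(9, 0.4)
  lamv <- as.numeric(eigen_spectrum(mv))
  Av <- as.matrix(generator(mv))
  for (i in c(1, 3)) {
    v <- eigenvectors_from_series(mv, lamv[i])
    expect_lt(max(abs(Av %*% v + lamv[i] * v)), 1e-8)
  }
  expect_error(eigenvectors_from_series(m, mean(lam[2:3])), "not an eigenvalue")
})

test_that("spectral evolution reconstructs t = 0, matches expm, and relaxes", {
  g <- fixture_birth_death(55, 18)
  P0 <- c(numeric(9), 1, numeric(9))
  P <- evolve(g, P0, c(0, 0.5, 3))
  expect_equal(unname(P[, 1]), P0, tolerance = 1e-12)
  for (k in 2:3) {
    expect_lt(max(abs(P[, k] - matrix_exponential_oracle(g, P0, c(0, 0.5, 3)[k]))),
              1e-8)
  }
  expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  expect_true(all(P > -1e-10))
  lam1 <- min(dense_spectrum_oracle(g)[-1])
  expect_lt(max(abs(evolve(g, P0, 60 / lam1)[, 1] - stationary_distribution(g))),
            1e-10)
  expect_error(evolve(g, P0 * 2, 1), "sum to 1")
})

test_that("matrix exponential oracle preserves mass and composes", {
  g <- fixture_birth_death(8, 10)
  P0 <- c(1, numeric(10))
  expect_equal(matrix_exponential_oracle(g, P0, 0), P0)
  P1 <- matrix_exponential_oracle(g, P0, 1)
  expect_equal(sum(P1), 1, tolerance = 1e-12)
  Ph <- matrix_exponential_oracle(g, matrix_exponential_oracle(g, P0, 0.5), 0.5)
  expect_lt(max(abs(Ph - P1)), 1e-10)
})

test_that("relaxation report sorts rates and flags the dominant time", {
  g <- birth_death_generator(c(0.8, 0), c(0, 1.7))
  rep2 <- relaxation_report(dense_spectrum_oracle(g))
  expect_identical(nrow(rep2), 1L)
  expect_equal(rep2$relaxation_time, 1 / 2.5)
  m <- binary_choice_model(10, 0.7, 1.3, 0.9, 1.7)
  tab <- relaxation_report(as.numeric(eigen_spectrum(m)))
  expect_true(!is.unsorted(tab$lambda))
  expect_true(all(diff(tab$relaxation_time) <= 0))
  expect_identical(which(tab$dominant), 1L)
})

test_that("asymmetric lambda_1 varies with N while the symmetric one does not", {
  sym <- vapply(c(5, 15), function(N) {
    lam <- as.numeric(eigen_spectrum(binary_choice_model(N, 1, 1, 0.7, 0.7)))
    min(lam[lam > 1e-8])
  }, numeric(1))
  expect_lt(abs(diff(sym)) / mean(sym), 1e-8)
  asym <- vapply(c(5, 15), function(N) {
    lam <- as.numeric(eigen_spectrum(binary_choice_model(N, 0.7, 1.3, 0.9, 1.7)))
    min(lam[lam > 1e-8])
  }, numeric(1))
  expect_gt(abs(diff(asym)) / mean(asym), 1e-3)
})

test_that("the fitted spectrum object supports the standard methods", {
  m <- binary_choice_model(9, 0.7, 1.3, 0.9, 1.7)
  fit <- spectral_decomposition(m)
  expect_s3_class(fit, "ctmc_spectrum")
  expect_identical(coef(fit)[1], 0)
  expect_output(print(fit), "dominant relaxation time")
  expect_output(print(summary(fit)), "Relaxation spectrum")
  expect_lt(max(residuals(fit)), 1e-10)
  P <- predict(fit, times = c(0.2, 2))
  expect_equal(dim(P), c(10L, 2L))
  expect_lt(max(abs(P[, 2] - matrix_exponential_oracle(fit$generator,
                                                       c(1, numeric(9)), 2))),
            1e-8)
  s <- simulate(fit, nsim = 200, seed = 4, n0 = 0, t_end = 0.5)
  expect_length(s, 200)
  pdf(NULL); plot(fit); dev.off()
  # dense route agrees with the recurrence route
  fit_d <- spectral_decomposition(m, method = "dense")
  expect_lt(max(abs(coef(fit_d) - coef(fit))), 1e-8)
})
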