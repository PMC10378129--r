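test_that("binary-choice generator rates and conservation", {
  m <- binary_choice_model(7, 0.7, 1.3, 0.9, 1.7)
  g <- generator(m)
  expect_equal(g$birth[1], 7 * 0.7)          # b(0) = N eps1
  expect_identical(g$death[1], 0)            # d(0) = 0
  expect_identical(g$birth[8], 0)            # b(N) = 0
  expect_equal(g$death[8], 7 * 1.3)          # d(N) = N eps2
  A <- as.matrix(g)
  expect_identical(diag(A), -(g$birth + g$death))  # exit rates negated exactly
  expect_lt(max(abs(colSums(A))), 1e-13)           # probability conservation
  # n <-> N-n symmetry under (eps1, mu1) <-> (eps2, mu2)
  g2 <- generator(binary_choice_model(7, 1.3, 0.7, 1.7, 0.9))
  expect_equal(g2$birth, rev(g$death))
  expect_equal(g2$death, rev(g$birth))
})

test_that("model constructors validate their domains", {
  expect_error(binary_choice_model(1, 1, 1, 1, 1))
  expect_error(binary_choice_model(5, 1, 1, 0, 1))
  expect_error(vacillating_voter_model(2, 0.5))
  expect_error(vacillating_voter_model(5, 0))
  expect_error(birth_death_generator(c(1, 1), c(0, 1)), "top state")
  expect_error(birth_death_generator(c(1, 0), c(1, 1)), "state 0")
})

test_that("vacillating generator boundary rates and symmetry", {
  m <- vacillating_voter_model(9, 0.35)
  g <- generator(m)
  expect_equal(g$birth[1], 9 * 0.35)         # only spontaneous flips at n = 0
  expect_identical(g$death[1], 0)
  expect_identical(g$birth[10], 0)
  expect_equal(g$death[10], 9 * 0.35)
  expect_equal(g$birth, rev(g$death))        # n <-> N-n symmetry
  # the recruitment part carries the full (1 - pd) factor
  m2 <- vacillating_voter_model(9, 0.999999)
  g2 <- generator(m2)
  expect_equal(g2$birth, 0.999999 * (9 - 0:9) +
                 (1 - 0.999999) * (9 - 0:9) * ((0:9) / 8) * (1 + (9 - 0:9) / 8))
})

test_that("the vacillating spectral recurrence reproduces its boundary row", {
  m <- vacillating_voter_model(11, 0.45)
  sr <- vacillating_recurrence(m)
  N <- 11; pd <- 0.45
  R0 <- (N - 1) * ((N - 1) * pd + N * (1 - pd))
  expect_equal(ttr_coef(sr$rec, 0, "R"), R0)
  expect_identical(ttr_coef(sr$rec, 0, "Qt"), 0)
  # C_1 = q(lambda) / R0 for any lambda
  lam <- 0.62
  q <- sr$q_of_lambda(lam)
  expect_equal(forward_substitution(sr$rec, 1, x = q)[2], q / R0)
  # in this basis the boundary override coincides with the generic row
  g <- generator(m)
  expect_equal(R0, (N - 1)^2 * g$death[2])
})

test_that("stationary distribution satisfies detailed balance and symmetry", {
  m <- binary_choice_model(30, 1, 1, 0.8, 0.8)
  g <- generator(m)
  pi_ <- stationary_distribution(g)
  expect_equal(sum(pi_), 1)
  expect_equal(pi_, rev(pi_))                       # symmetric model
  expect_lt(max(abs(as.matrix(g) %*% pi_)), 1e-12)  # A pi = 0
  g100 <- generator(binary_choice_model(100, 0.4, 1.1, 0.6, 1.4))
  pi100 <- stationary_distribution(g100)
  expect_lt(max(abs(as.matrix(g100) %*% pi100)), 1e-12)
  bad <- birth_death_generator(c(1, 0, 1, 0), c(0, 1, 1, 1))
  expect_error(stationary_distribution(bad), "n = 1")
})

test_that("SSA is reproducible, frozen chains stay put, and long runs reach stationarity", {
  g <- generator(binary_choice_model(8, 0.6, 1.1, 0.7, 1.2))
  s1 <- gillespie_simulate(g, 0, 1, 500, seed = 42)
  s2 <- gillespie_simulate(g, 0, 1, 500, seed = 42)
  expect_identical(s1, s2)
  g0 <- birth_death_generator(numeric(4), numeric(4))
  expect_identical(unique(gillespie_simulate(g0, 2, 5, 50, seed = 1)), 2L)
  slong <- gillespie_simulate(g, 4, 60, 20000, seed = 9)
  emp <- tabulate(slong + 1L, nbins = 9) / 20000
  expect_lt(tv_dist(emp, stationary_distribution(g)), 0.02)
})

test_that("rule-based vacillating simulation matches the propensity chain", {
  m <- vacillating_voter_model(12, 0.5)
  s <- vacillating_rule_simulate(m, n_steps = 3e5, seed = 5, burnin = 2000)
  s <- s[seq(10, length(s), by = 10)]
  emp <- tabulate(s + 1L, nbins = 13) / length(s)
  expect_lt(tv_dist(emp, stationary_distribution(generator(m))), 0.03)
  # determinism
  a <- vacillating_rule_simulate(m, 100, seed = 3)
  b <- vacillating_rule_simulate(m, 100, seed = 3)
  expect_identical(a, b)
})

test_that("stationary trimodality appears at small spontaneous-flip rates", {
  pi_ <- stationary_distribution(generator(vacillating_voter_model(20, 0.05)))
  expect_gte(count_modes(pi_), 3)
  # and disappears deep in the noise-dominated regime
  pi2 <- stationary_distribution(generator(vacillating_voter_model(20, 0.9)))
  expect_identical(count_modes(pi2), 1L)
})
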