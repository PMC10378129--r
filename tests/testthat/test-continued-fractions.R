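test_that("backward ladder honors its truncation and first rung", {
  rec <- fixture_recurrence(11, i_max = 10, mode = "double")
  lam <- 0.83
  lad <- backward_ladder(rec, lam, 7)
  expect_identical(lad$S[8], 0)
  expect_equal(lad$S[7],
               -ttr_coef(rec, 7, "P") / (lam - ttr_coef(rec, 7, "Qt")))
  # N = 2: two unrollings by hand
  lad2 <- backward_ladder(rec, lam, 2)
  hand <- -ttr_coef(rec, 1, "P") /
    ((lam - ttr_coef(rec, 1, "Qt")) + ttr_coef(rec, 1, "R") *
       (-ttr_coef(rec, 2, "P") / (lam - ttr_coef(rec, 2, "Qt"))))
  expect_equal(lad2$S[1], hand)
})

test_that("ladder pole errors carry the failing index", {
  rec <- three_term_recurrence(function(j) 1, function(j) 2, function(j) 1)
  # lambda = Qt_N makes the last denominator vanish
  expect_error(backward_ladder(rec, 2, 4), "pole at j = 3")
})

test_that("coefficients from the ladder start at C0 and end at zero", {
  rec <- fixture_recurrence(12, i_max = 8, mode = "double")
  lad <- backward_ladder(rec, -0.4, 5)
  C <- coefficients_from_ladder(lad, C0 = 2.5)
  expect_length(C, 7)
  expect_identical(C[1], 2.5)
  expect_identical(C[7], 0)
})

test_that("at an eigenvalue the ladder reproduces the truncating eigencoefficients", {
  m <- binary_choice_model(6, 0.7, 1.3, 0.9, 1.7)
  g <- generator(m)
  b <- g$birth; d <- g$death
  rec <- three_term_recurrence(P = function(j) if (j >= 1) b[j] else 0,
                               Qt = function(j) b[j + 1] + d[j + 1],
                               R = function(j) d[j + 2])
  lam <- dense_spectrum_oracle(g)[3]   # a genuinely decaying mode
  lad <- backward_ladder(rec, lam, 6)
  C_lad <- coefficients_from_ladder(lad)
  rec_sh <- three_term_recurrence(P = function(j) if (j >= 1) b[j] else 0,
                                  Qt = function(j) b[j + 1] + d[j + 1] - lam,
                                  R = function(j) d[j + 2])
  C_fwd <- forward_substitution(rec_sh, 6)
  u <- C_lad[1:7] / sqrt(sum(C_lad[1:7]^2))
  v <- C_fwd / sqrt(sum(C_fwd^2))
  if (sum(u * v) < 0) v <- -v
  expect_lt(max(abs(u - v)), 1e-8)                 # proportional sequences
  expect_lt(abs(C_lad[8]) / max(abs(C_lad)), 1e-9) # C~_{N+1} = 0
})

test_that("the continued-fraction/rational-fraction identity holds exactly and in floats", {
  worst <- 0
  for (f in 1:8) {
    N <- 4 + (f %% 6)
    rex <- fixture_recurrence(300 + f, i_max = N + 2)
    red <- fixture_recurrence(300 + f, i_max = N + 2, mode = "double")
    for (k in 1:6) {
      qq <- c(sample(-20:20, 1), sample(1:7, 1))
      gap_e <- try(rational_identity_gap(rex, qq, N), silent = TRUE)
      if (!inherits(gap_e, "try-error")) expect_identical(gap_e, 0)
      gap_f <- try(rational_identity_gap(red, qq[1] / qq[2], N), silent = TRUE)
      if (!inherits(gap_f, "try-error")) worst <- max(worst, gap_f)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("the identity at N = 2 matches the hand-unrolled fraction", {
  rec <- three_term_recurrence(function(j) 3, function(j) 2, function(j) 1.5)
  q <- 0.7
  lhs <- 1 / ((2 + q) - 1.5 * 3 / (2 + q))
  ph <- phi_family(rec, 2, q)$values
  expect_equal(ph[2] / ph[3], lhs, tolerance = 1e-14)
  expect_lt(rational_identity_gap(rec, q, 2), 1e-14)
})

test_that("both sides of the identity vanish as q grows (degree bookkeeping)", {
  rec <- fixture_recurrence(14, i_max = 8, mode = "double")
  ph <- phi_family(rec, 6, 1e8)$values
  expect_lt(abs(ph[6] / ph[7]), 1e-7)   # ratio ~ 1/q
})
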