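test_that("phi family satisfies its base cases and the hand-expanded j = 2 value", {
  rec <- const_rec()
  expect_identical(phi_family(rec, 3, 7)$values[1], 1)       # phi_0^i = 1
  x <- 0.37
  qrec <- three_term_recurrence(function(j) j + 1, function(j) j^2 - 2,
                                function(j) j + 0.5)
  expect_equal(phi_family(qrec, 3, x)$values[2], x + (3^2 - 2))  # phi_1^i = x + Qt_i
  # constant family: phi_2^2(0) = Qt_1 Qt_2 - R_1 P_2 = 4 - 1 = 3
  expect_equal(phi_family(rec, 2, 0)$values[3], 3)
})

test_that("symbolic phi polynomials are monic of exact degree j", {
  rec <- fixture_recurrence(31, i_max = 12, mode = "double")
  ph <- phi_family(rec, 10, x = NULL)
  for (j in 0:10) {
    co <- ph[[j + 1]]
    expect_length(co, j + 1)
    expect_identical(co[j + 1], 1)   # unit leading coefficient, exactly
  }
})

test_that("closed form reproduces boundary values and the constant family", {
  rec <- const_rec()
  expect_identical(closed_form_C(rec, 0), 1)
  expect_equal(closed_form_C(rec, 1), 2)   # Qt_0 / R_0
  expect_equal(vapply(0:6, function(i) closed_form_C(rec, i), numeric(1)),
               as.numeric(1:7))
  expect_identical(forward_substitution(rec, 0), 1)
  expect_equal(forward_substitution(rec, 3), c(1, 2, 3, 4))
})

test_that("closed form equals the forward-substitution oracle exactly on rational families", {
  for (f in 1:20) {
    rec <- fixture_recurrence(900 + f, i_max = 40)
    fw <- forward_substitution(rec, 40)
    for (i in seq(0, 40, by = 4)) {
      expect_true(eq_equal(closed_form_C(rec, i), fw[[i + 1]]),
                  label = sprintf("family %d, i = %d", f, i))
    }
  }
})

test_that("double-precision closed form tracks the exact tier to 1e-8 up to i = 25", {
  for (f in 1:5) {
    rex <- fixture_recurrence(50 + f, i_max = 26)
    red <- fixture_recurrence(50 + f, i_max = 26, mode = "double")
    ex <- vapply(forward_substitution(rex, 25), as.numeric, numeric(1))
    for (i in c(5, 15, 25)) {
      got <- closed_form_C(red, i)
      expect_lt(abs(got - ex[i + 1]) / max(1e-300, abs(ex[i + 1])), 1e-8)
    }
  }
})

test_that("closed form agrees with a raw-table oracle on arbitrary real families", {
  set.seed(4)
  for (f in 1:10) {
    pv <- runif(20, -2, 2); qv <- runif(20, -2, 2); rv <- runif(20, 0.4, 2)
    rec <- three_term_recurrence(pv, qv, rv)
    want <- raw_forward(function(j) pv[j + 1], function(j) qv[j + 1],
                        function(j) rv[j + 1], 15)
    got <- vapply(0:15, function(i) closed_form_C(rec, i), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the solution is invariant under a common rescaling of all coefficients", {
  set.seed(9)
  pv <- runif(15, -2, 2); qv <- runif(15, -2, 2); rv <- runif(15, 0.4, 2)
  base <- forward_substitution(three_term_recurrence(pv, qv, rv), 12)
  for (cc in c(0.01, 3, -7, 250)) {
    scaled <- forward_substitution(
      three_term_recurrence(cc * pv, cc * qv, cc * rv), 12)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("inverse-column elements match their definitions and reconstruct C_i", {
  rec <- const_rec()
  expect_equal(inverse_column_elements(rec, 1)$theta1, 1)   # phi_0^0(0)/R_0
  ic2 <- inverse_column_elements(rec, 2)
  expect_equal(ic2$theta1, 2)
  expect_equal(ic2$theta2, 1)
  # consistency C_i = Qt_0 theta_{i,1} - P_1 theta_{i,2} on a random family
  rec <- fixture_recurrence(77, i_max = 14, mode = "double")
  fw <- forward_substitution(rec, 12)
  for (i in c(1, 4, 9, 12)) {
    ic <- inverse_column_elements(rec, i)
    got <- ttr_coef(rec, 0, "Qt") * ic$theta1 - ttr_coef(rec, 1, "P") * ic$theta2
    expect_equal(got, fw[i + 1], tolerance = 1e-9)
  }
})

test_that("row overrides take effect before any evaluation", {
  rec <- three_term_recurrence(function(j) 1, function(j) 2, function(j) 1,
                               overrides = list("0" = list(Qt = 5, R = 2)))
  expect_identical(ttr_coef(rec, 0, "Qt"), 5)
  expect_identical(ttr_coef(rec, 1, "Qt"), 2)
  expect_equal(closed_form_C(rec, 1), 5 / 2)
  expect_equal(forward_substitution(rec, 1)[2], 5 / 2)
})

test_that("domain and singularity errors are informative", {
  rec <- const_rec()
  expect_error(phi_family(rec, -1, 0), "nonnegative")
  expect_error(closed_form_C(rec, -2), "nonnegative")
  expect_error(inverse_column_elements(rec, 0), "i = 0")
  bad <- three_term_recurrence(function(j) 1, function(j) 2,
                               function(j) ifelse(j == 2, 0, 1))
  expect_error(closed_form_C(bad, 5), "R_2 = 0")
  expect_error(forward_substitution(bad, 5), "R_2 = 0")
  short <- three_term_recurrence(P = c(1, 1), Qt = c(2, 2), R = c(1, 1))
  expect_error(forward_substitution(short, 5), "no entry at index j = 2")
  exact_bad <- three_term_recurrence(function(j) 0.5, function(j) 2,
                                     function(j) 1, mode = "exact")
  expect_error(forward_substitution(exact_bad, 3), "integer or rational")
})

test_that("exact fractions convert and print sensibly", {
  rec <- fixture_recurrence(5, i_max = 10)
  v <- closed_form_C(rec, 8)
  expect_s3_class(v, "ttr_fraction")
  expect_true(is.finite(as.numeric(v)))
  expect_match(as.character(v), "^-?[0-9]+/-?[0-9]+$")
  recd <- fixture_recurrence(5, i_max = 10, mode = "double")
  expect_equal(as.numeric(v), closed_form_C(recd, 8), tolerance = 1e-10)
})
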