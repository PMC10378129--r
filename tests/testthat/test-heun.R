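test_that("parameter containers enforce their invariants", {
  expect_error(general_heun(a = 0, q = 1, alpha = 1, beta = 1, gamma = 1,
                            delta = 0), "degenerate singularity")
  expect_error(general_heun(a = 2, q = 1, alpha = 1, beta = 1, gamma = -2,
                            delta = 0), "singular gamma")
  expect_error(confluent_heun(q = 1, alpha = 1, gamma = 0, delta = 0,
                              epsilon = 1), "singular gamma")
  expect_error(general_heun(a = 2, q = 1, alpha = 1, beta = 1, gamma = 0.5,
                            delta = 0, epsilon = 99), "Fuchs")
  p <- general_heun(a = 2, q = 1, alpha = -3, beta = 0.4, gamma = 0.5,
                    delta = 0.2)
  expect_equal(p$epsilon, p$alpha + p$beta + 1 - p$gamma - p$delta)
})

test_that("first series coefficients follow the recurrence boundary rows", {
  p <- general_heun(a = 1.7, q = 0.9, alpha = -4, beta = 0.3, gamma = 1.2,
                    delta = 0.5)
  rec <- heun_recurrence(p, include_accessory = FALSE)
  expect_equal(ttr_coef(rec, 0, "R"), p$a * p$gamma)       # R_0 = a gamma
  expect_identical(ttr_coef(rec, 0, "Qt"), 0)              # Qt_0 = q alone
  expect_equal(heun_series(p, 1)$coefficients[2],
               p$q / (p$a * p$gamma))                      # C_1 = q/(a gamma)
  pc <- confluent_heun(q = 0.8, alpha = -1.1, gamma = 1.4, delta = 0.3,
                       epsilon = 0.6)
  recc <- heun_recurrence(pc, include_accessory = FALSE)
  expect_equal(ttr_coef(recc, 0, "R"), pc$gamma)
  expect_equal(heun_series(pc, 1)$coefficients[2], pc$q / pc$gamma)
  # middle coefficient at j = 1 as the differential equation dictates
  expect_equal(ttr_coef(recc, 1, "Qt"),
               pc$gamma + pc$delta - pc$epsilon)
})

test_that("closed-form series equals forward substitution of the shifted family", {
  for (f in 1:6) {
    type <- if (f %% 2) "general" else "confluent"
    p <- fixture_heun(600 + f, type)
    rec <- heun_recurrence(p, include_accessory = TRUE)
    fw <- forward_substitution(rec, 30)
    cs <- heun_series(p, 30)$coefficients
    expect_equal(cs, fw, tolerance = 1e-9)
  }
})

test_that("the confluent family is the a -> Inf limit of the general family", {
  a <- 1e8; eps_c <- 0.8; q_c <- 0.37; ga <- 1.9; de <- 0.4; al_g <- -2.2
  eps_g <- -eps_c * a
  be_g <- eps_g + ga + de - 1 - al_g
  pg <- general_heun(a = a, q = q_c * a, alpha = al_g, beta = be_g,
                     gamma = ga, delta = de)
  pc <- confluent_heun(q = q_c, alpha = -al_g * be_g / a, gamma = ga,
                       delta = de, epsilon = eps_c)
  rg <- heun_recurrence(pg); rc <- heun_recurrence(pc)
  for (j in 0:5) {
    expect_equal(ttr_coef(rg, j, "P") / a, ttr_coef(rc, j, "P"),
                 tolerance = 1e-5)
    expect_equal(ttr_coef(rg, j, "Qt") / a, ttr_coef(rc, j, "Qt"),
                 tolerance = 1e-5)
    expect_equal(ttr_coef(rg, j, "R") / a, ttr_coef(rc, j, "R"),
                 tolerance = 1e-5)
  }
  expect_lt(max(abs(heun_series(pg, 12)$coefficients -
                      heun_series(pc, 12)$coefficients)), 1e-6)
})

test_that("a trivial constant solution has exactly zero residual", {
  pc <- confluent_heun(q = 0, alpha = 0, gamma = 1.3, delta = 0.4,
                       epsilon = 0.7)
  ser <- heun_series(pc, 10)
  expect_equal(ser$coefficients, c(1, numeric(10)))
  expect_identical(heun_ode_residual(ser, c(0.2, -0.15, 0.3i)), 0)
})

test_that("the ODE residual decays geometrically with truncation order", {
  p <- fixture_heun(41, "general")
  res <- vapply(c(10, 20, 30), function(n)
    heun_ode_residual(heun_series(p, n), 0.25 * min(1, abs(p$a))), numeric(1))
  expect_lt(res[2], res[1] * 1e-2)
  expect_lt(res[3], 1e-10)
})

test_that("corrupting one coefficient inflates the residual by orders of magnitude", {
  p <- fixture_heun(77, "general")
  ser <- heun_series(p, 40)
  clean <- heun_ode_residual(ser, 0.2)
  ser$coefficients[3] <- ser$coefficients[3] + 1e-3
  expect_gt(heun_ode_residual(ser, 0.2), max(clean, 1e-15) * 1e3)
})

test_that("heun_eval is guarded, converges, and matches the IVP oracle", {
  p <- fixture_heun(19, "general")
  expect_identical(heun_eval(p, 0)$value, 1)
  expect_error(heun_eval(p, 0.999 * 2), "convergence-domain")
  worst <- 0
  for (f in 1:10) {
    type <- if (f %% 2) "general" else "confluent"
    pp <- fixture_heun(800 + f, type)
    r <- if (type == "general") min(1, abs(pp$a)) else 1
    ev <- heun_eval(pp, 0.3 * r)
    expect_true(ev$converged)
    worst <- max(worst, abs(ev$value - heun_ode_oracle(pp, 0.3 * r)))
  }
  expect_lt(worst, 1e-8)
})

test_that("a vanishing accessory parameter kills the linear term", {
  p <- general_heun(a = 2.5, q = 0, alpha = -3, beta = 0.4, gamma = 0.8,
                    delta = 0.1)
  cs <- heun_series(p, 3)$coefficients
  expect_identical(cs[2], 0)                      # C_1 = q/(a gamma) = 0
  z <- 1e-3
  expect_lt(abs(heun_eval(p, z)$value - 1), 10 * abs(cs[3]) * z^2)
})

test_that("quantized accessory parameters truncate the series to a polynomial", {
  m <- binary_choice_model(5, 0.7, 1.3, 0.9, 1.7)
  lam <- as.numeric(eigen_spectrum(m))
  srec <- spectral_recurrence(m)
  q1 <- srec$q_of_lambda(lam[2])
  C <- forward_substitution(srec$rec, 8, x = q1)
  expect_lt(max(abs(C[7:9])) / max(abs(C)), 1e-9)  # C_j = 0 beyond N = 5
  # evaluation outside the nominal disc is allowed for the polynomial
  map <- binary_choice_heun_map(m)
  pstar <- map$params_at(lam[2])
  ev <- heun_eval(pstar, 2.0)
  expect_true(ev$converged)
  expect_equal(ev$value, sum(C[1:6] * 2.0^(0:5)), tolerance = 1e-8)
})

test_that("an engineered integer family truncates exactly in exact arithmetic", {
  # family P = R = 1, Qt = x: C_1 = x, C_2 = x^2 - 1, C_3 = x(x^2 - 2);
  # at x = 0 the truncation condition C_3 = 0 holds exactly
  rec <- three_term_recurrence(function(j) 1, function(j) 0, function(j) 1,
                               mode = "exact")
  C <- forward_substitution(rec, 3, x = 0)
  expect_match(as.character(C[[4]]), "^0/")
  expect_match(as.character(closed_form_C(rec, 3, x = 0)), "^0/")
  expect_true(eq_equal(closed_form_C(rec, 3, x = 0), C[[4]]))
})
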