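# Cross-oracle validation suite: every invariant that ties the closed
# form, the continued fractions, the Heun series, the quantization
# spectrum, and the stochastic oracles together, run on freshly generated
# seeded fixtures.

.vrec <- function(property, n, value, threshold, comparison = "le") {
  pass <- switch(comparison, le = value <= threshold, ge = value >= threshold)
  list(property = property, n = n, value = value, threshold = threshold,
       comparison = comparison, pass = pass)
}

#' Run the cross-oracle validation suite
#'
#' Executes the package's full set of cross-checks on seeded random
#' fixtures: exact closed-form vs forward-substitution equality, the
#' continued-fraction / orthogonal-polynomial identity, quantization
#' spectra against dense eigensolves for both choice models, the
#' symmetric-model invariance of the slowest relaxation rate, Heun series
#' ODE residuals and the initial-value oracle, spectral time evolution
#' against the matrix exponential, stationarity/trimodality of the
#' vacillating voter model, and agreement of the rule-based and SSA
#' simulations with the analytic distributions.
#'
#' @param seed master seed; all fixture seeds derive from it.
#' @param level `"full"` (validation-grade sample sizes) or `"quick"`
#'   (reduced sizes for interactive use).
#' @param out optional path; the report is additionally written there as
#'   JSON.
#' @return Object of class `"validation_report"`: a list of records with
#'   `property`, `n`, `value`, `threshold`, `comparison`, `pass`.
#' @export
run_validation_suite <- function(seed = 1, level = c("full", "quick"),
                                 out = NULL) {
  level <- match.arg(level)
  q <- level == "quick"
  seed <- as.integer(seed)
  R <- list()

  ## 1. closed form vs forward substitution, exact arithmetic
  nfam <- if (q) 20 else 200
  imax <- 40
  mism <- 0L
  for (f in seq_len(nfam)) {
    rec <- fixture_recurrence(seed * 1000L + f, i_max = imax)
    fw <- forward_substitution(rec, imax)
    for (i in seq(0, imax, by = if (q) 8 else 1)) {
      cf <- closed_form_C(rec, i)
      if (!eq_equal(cf, fw[[i + 1L]])) mism <- mism + 1L
    }
  }
  R[[length(R) + 1L]] <- .vrec("closed_form_equals_forward_exact",
                               nfam, mism, 0)

  ## 2. continued-fraction identity, exact and float
  nfam2 <- if (q) 8 else 50
  gap_exact <- 0; gap_float <- 0
  for (f in seq_len(nfam2)) {
    N <- sample(2:12, 1)
    rec <- fixture_recurrence(seed * 2000L + f, i_max = N + 2L)
    recd <- fixture_recurrence(seed * 2000L + f, i_max = N + 2L, mode = "double")
    for (k in 1:10) {
      qq <- c(sample(-30:30, 1), sample(1:9, 1))
      g <- try(rational_identity_gap(rec, qq, N), silent = TRUE)
      if (!inherits(g, "try-error")) gap_exact <- max(gap_exact, g)
      lhs_ok <- try({
        gf <- rational_identity_gap(recd, qq[1] / qq[2], N)
        ph <- phi_family(recd, N, qq[1] / qq[2])$values
        gap_float <- max(gap_float, gf / max(1e-300, abs(ph[N] / ph[N + 1L])))
      }, silent = TRUE)
    }
  }
  R[[length(R) + 1L]] <- .vrec("cf_identity_gap_exact", nfam2, gap_exact, 0)
  R[[length(R) + 1L]] <- .vrec("cf_identity_relgap_float", nfam2, gap_float, 1e-10)

  ## 3. binary-choice quantization spectrum vs dense oracle
  Ns <- if (q) c(3, 5, 10) else c(3, 5, 10, 20)
  ndraw <- if (q) 4 else 20
  set.seed(seed + 3L)
  dev3 <- 0
  for (N in Ns) for (d in seq_len(ndraw)) {
    r4 <- stats::runif(4, 0.1, 2)
    m <- binary_choice_model(N, r4[1], r4[2], r4[3], r4[4])
    lam <- suppressWarnings(as.numeric(eigen_spectrum(m)))
    ref <- dense_spectrum_oracle(generator(m))
    dev3 <- max(dev3, max(abs(lam - ref)))
  }
  R[[length(R) + 1L]] <- .vrec("binary_spectrum_vs_dense",
                               length(Ns) * ndraw, dev3, 1e-6)

  ## 4. symmetric-model law and asymmetric contrast
  lam1 <- c()
  for (N in c(5, 10, 20, 40)) for (mu in c(0.5, 1, 2)) {
    m <- binary_choice_model(N, 1, 1, mu, mu)
    lam <- suppressWarnings(as.numeric(eigen_spectrum(m)))
    lam1 <- c(lam1, min(lam[lam > 1e-8]))
  }
  spread <- (max(lam1) - min(lam1)) / mean(lam1)
  R[[length(R) + 1L]] <- .vrec("symmetric_lambda1_rel_spread", 12, spread, 1e-8)
  asym <- vapply(c(5, 10, 20), function(N) {
    lam <- dense_spectrum_oracle(generator(
      binary_choice_model(N, 0.7, 1.3, 0.9, 1.7)))
    min(lam[lam > 1e-8])
  }, numeric(1))
  rel_change <- (max(asym) - min(asym)) / mean(asym)
  R[[length(R) + 1L]] <- .vrec("asymmetric_lambda1_rel_change", 3,
                               rel_change, 1e-3, "ge")

  ## 5. Heun series: ODE residual and initial-value oracle
  nheun <- if (q) 12 else 100
  res5 <- 0; ivp5 <- 0
  for (f in seq_len(nheun)) {
    type <- if (f %% 2 == 0) "general" else "confluent"
    p <- fixture_heun(seed * 5000L + f, type)
    r <- if (type == "general") min(1, abs(p$a)) else 1
    ser <- heun_series(p, 40)
    res5 <- max(res5, heun_ode_residual(ser, c(0.2 * r, -0.2 * r)))
    z <- 0.3 * r
    ivp5 <- max(ivp5, abs(heun_eval(p, z)$value - heun_ode_oracle(p, z)))
  }
  R[[length(R) + 1L]] <- .vrec("heun_ode_residual_order40", nheun, res5, 1e-10)
  R[[length(R) + 1L]] <- .vrec("heun_eval_vs_ivp_oracle", nheun, ivp5, 1e-8)

  ## 6. spectral evolution vs matrix exponential
  nchain <- if (q) 3 else 8
  dev6 <- 0; colsum6 <- 0; tinf6 <- 0
  for (f in seq_len(nchain)) {
    set.seed(seed * 6000L + f)
    N <- sample(5:30, 1)
    g <- fixture_birth_death(seed * 6000L + f, N)
    P0 <- as.numeric(stats::rmultinom(1, 1, rep(1, N + 1))) # random point mass
    P <- evolve(g, P0, c(0.1, 1, 10))
    for (k in seq_along(c(0.1, 1, 10))) {
      ref <- matrix_exponential_oracle(g, P0, c(0.1, 1, 10)[k])
      dev6 <- max(dev6, max(abs(P[, k] - ref)))
    }
    colsum6 <- max(colsum6, max(abs(colSums(P) - 1)))
    lam1 <- min(dense_spectrum_oracle(g)[-1])  # t -> Inf means t >> 1/lambda_1
    tinf6 <- max(tinf6, max(abs(evolve(g, P0, 50 / lam1)[, 1] -
                                  stationary_distribution(g))))
  }
  R[[length(R) + 1L]] <- .vrec("evolve_vs_expm_supnorm", nchain, dev6, 1e-8)
  R[[length(R) + 1L]] <- .vrec("evolve_column_sums", nchain, colsum6, 1e-10)
  R[[length(R) + 1L]] <- .vrec("evolve_tinf_vs_stationary", nchain, tinf6, 1e-10)

  ## 7. vacillating voter: spectrum, rule-based ABM, trimodality
  dev7 <- 0
  for (N in c(5, 10, 15)) for (pd in c(0.1, 0.5, 0.9)) {
    m <- vacillating_voter_model(N, pd)
    lam <- suppressWarnings(as.numeric(eigen_spectrum(m)))
    ref <- dense_spectrum_oracle(generator(m))
    dev7 <- max(dev7, max(abs(lam - ref)))
  }
  R[[length(R) + 1L]] <- .vrec("vacillating_spectrum_vs_dense", 9, dev7, 1e-6)
  mva <- vacillating_voter_model(15, 0.5)
  nsamp <- if (q) 2e4 else 1e5
  thin <- if (q) 5L else 20L
  states <- vacillating_rule_simulate(mva, n_steps = nsamp * thin,
                                      seed = seed + 7L, burnin = 5000L)
  states <- states[seq(thin, length(states), by = thin)]
  emp <- tabulate(states + 1L, nbins = mva$N + 1L) / length(states)
  tv7 <- 0.5 * sum(abs(emp - stationary_distribution(generator(mva))))
  R[[length(R) + 1L]] <- .vrec("vacillating_abm_tv", nsamp, tv7, 0.02)
  pist <- stationary_distribution(generator(vacillating_voter_model(20, 0.05)))
  is_max <- vapply(seq_along(pist), function(i) {
    l <- if (i > 1) pist[i - 1] else -Inf
    r <- if (i < length(pist)) pist[i + 1] else -Inf
    pist[i] > l && pist[i] > r
  }, logical(1))
  R[[length(R) + 1L]] <- .vrec("vacillating_stationary_modes", 1,
                               sum(is_max), 3, "ge")

  ## 8. SSA vs matrix exponential
  g8 <- generator(binary_choice_model(10, 0.7, 1.3, 0.9, 1.7))
  ntraj <- if (q) 2e4 else 1e5
  ssa <- gillespie_simulate(g8, n0 = 0, t_end = 1, n_traj = ntraj,
                            seed = seed + 8L)
  emp8 <- tabulate(ssa + 1L, nbins = 11L) / ntraj
  ref8 <- matrix_exponential_oracle(g8, c(1, numeric(10)), 1)
  tv8 <- 0.5 * sum(abs(emp8 - ref8))
  R[[length(R) + 1L]] <- .vrec("gillespie_tv_vs_expm", ntraj, tv8, 0.02)

  report <- structure(list(seed = seed, level = level, records = R),
                      class = "validation_report")
  if (!is.null(out)) {
    jsonlite::write_json(list(seed = seed, level = level, records = R),
                         out, auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation suite (seed ", x$seed, ", ", x$level, ")\n", sep = "")
  for (r in x$records) {
    cat(sprintf("  %-34s n=%-7g value=%-12.4g %s %-8g  %s\n",
                r$property, r$n, r$value,
                if (r$comparison == "le") "<=" else ">=",
                r$threshold, if (r$pass) "PASS" else "FAIL"))
  }
  fails <- sum(!vapply(x$records, `[[`, logical(1), "pass"))
  cat(if (fails == 0) "all properties pass\n"
      else paste0(fails, " propert(ies) FAILED\n"))
  invisible(x)
}

#' Did every validation property pass?
#' @param report a [run_validation_suite()] result.
#' @export
validation_passed <- function(report) {
  all(vapply(report$records, `[[`, logical(1), "pass"))
}
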