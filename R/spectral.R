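# Eigenspectrum machinery: the accessory-parameter quantization polynomial
# built symbolically from the orthogonal polynomials, its root solver with
# recursion-based Newton polishing, dense oracles, series eigenvectors,
# and spectral / matrix-exponential time evolution.

.as_srec <- function(x, N = NULL) {
  if (inherits(x, "spectral_recurrence")) return(x)
  if (inherits(x, "choice_model")) return(spectral_recurrence(x))
  if (inherits(x, "ttr")) {
    stopifnot(!is.null(N))
    return(structure(list(rec = x, N = N,
                          q_of_lambda = identity, lambda_of_q = identity,
                          model = NULL),
                     class = "spectral_recurrence"))
  }
  stop("expected a spectral_recurrence, choice model, or ttr")
}

#' Accessory-parameter quantization polynomial
#'
#' Builds, symbolically in the accessory parameter \eqn{q}, the monic
#' degree-`N + 1` polynomial
#' \deqn{(Q_0 + q)\,\phi_N^N(q) - R_0 P_1\, \phi_{N-1}^N(q)}
#' whose roots enforce the series truncation \eqn{C_{N+1} = 0} and hence
#' define the `N + 1` quantized accessory parameters (the eigenvalue
#' spectrum, after mapping \eqn{q \to \lambda}).  The orthogonal
#' polynomials are expanded through their recursion on coefficient
#' vectors; row overrides of the recurrence (boundary rows) are honored.
#'
#' @param x a [spectral_recurrence()], a choice model, or a bare
#'   accessory-free [three_term_recurrence()] (then `N` is required).
#' @param N truncation index when `x` is a bare recurrence.
#' @return Numeric coefficient vector, ascending powers, length `N + 2`,
#'   with leading coefficient exactly 1.
#' @export
quantization_polynomial <- function(x, N = NULL) {
  srec <- .as_srec(x, N)
  rec <- srec$rec; N <- srec$N
  ph <- .phi_all_poly(rec, N)
  top <- ph[[N + 1L]]            # phi_N^N
  prev <- if (N >= 1L) ph[[N]] else 0   # phi_{N-1}^N
  q0 <- ttr_coef(rec, 0L, "Qt")
  r0p1 <- ttr_coef(rec, 0L, "R") * ttr_coef(rec, 1L, "P")
  out <- numeric(N + 2L)
  out[2:(N + 2L)] <- out[2:(N + 2L)] + top            # q * phi_N^N
  out[seq_along(top)] <- out[seq_along(top)] + q0 * top
  out[seq_along(prev)] <- out[seq_along(prev)] - r0p1 * prev
  if (!all(is.finite(out)))
    stop("quantization polynomial coefficients overflowed double precision; ",
         "reduce N or rescale the model rates", call. = FALSE)
  out
}

# F(q) and F'(q) evaluated through the phi recursion (renormalized), for
# Newton polishing: much better conditioned than the expanded coefficients.
.quant_eval_deriv <- function(rec, N, q) {
  f_prev <- 1; f_prev_d <- 0          # phi_0
  f_top <- q + ttr_coef(rec, N, "Qt"); f_top_d <- 1   # phi_1
  if (N == 0L) { f_top <- 1; f_top_d <- 0; f_prev <- 0; f_prev_d <- 0 }
  if (N >= 2L) for (j in 2L:N) {
    k <- N - (j - 1L)
    qt <- ttr_coef(rec, k, "Qt")
    cc <- ttr_coef(rec, k, "R") * ttr_coef(rec, k + 1L, "P")
    new <- (qt + q) * f_top - cc * f_prev
    new_d <- f_top + (qt + q) * f_top_d - cc * f_prev_d
    f_prev <- f_top; f_prev_d <- f_top_d
    f_top <- new; f_top_d <- new_d
    m <- max(abs(f_top), abs(f_prev), abs(f_top_d), abs(f_prev_d))
    if (m > 1e200) {
      s <- 1e-200
      f_top <- f_top * s; f_prev <- f_prev * s
      f_top_d <- f_top_d * s; f_prev_d <- f_prev_d * s
    }
  }
  q0 <- ttr_coef(rec, 0L, "Qt")
  r0p1 <- ttr_coef(rec, 0L, "R") * ttr_coef(rec, 1L, "P")
  FF <- (q0 + q) * f_top - r0p1 * f_prev
  FD <- f_top + (q0 + q) * f_top_d - r0p1 * f_prev_d
  c(FF, FD)
}

# roots of the quantization polynomial: scaled companion solve (polyroot)
# followed by Newton polishing through the recursion evaluation
.quant_roots <- function(srec) {
  rec <- srec$rec; N <- srec$N
  co <- quantization_polynomial(srec)
  deg <- N + 1L
  mags <- abs(co[1:deg])
  nz <- mags > 0
  s <- if (any(nz)) max((mags[nz])^(1 / (deg - which(nz) + 1))) else 1
  if (!is.finite(s) || s <= 0) s <- 1
  cs <- co * s^(0:(deg))
  cs <- cs / cs[deg + 1L]
  if (max(abs(cs)) > 1e280)
    warning("ill-conditioned quantization polynomial (coefficient spread > 1e280)")
  rts <- polyroot(cs) * s
  q <- Re(rts)
  for (k in seq_along(q)) {
    for (it in 1:6) {
      fd <- .quant_eval_deriv(rec, N, q[k])
      if (!is.finite(fd[2]) || fd[2] == 0) break
      step <- fd[1] / fd[2]
      q[k] <- q[k] - step
      if (abs(step) <= 1e-14 * (1 + abs(q[k]))) break
    }
  }
  sort(q)
}

#' Relaxation spectrum of a choice model from the quantization polynomial
#'
#' Finds the roots \eqn{q^\ast} of the quantization polynomial of the
#' model's spectral recurrence and maps them to decay rates
#' (binary choice: \eqn{\lambda = N\epsilon_1 + \mu_1 q^\ast};
#' vacillating voter: \eqn{\lambda = p_d N - q^\ast/(N-1)}).  The zero
#' mode is snapped to exactly 0 when within `1e-10` of the spectral
#' radius; repeated roots within tolerance trigger a multiplicity warning.
#'
#' @param model a [binary_choice_model()] or [vacillating_voter_model()].
#' @return Sorted numeric vector of `N + 1` decay rates, starting at 0,
#'   with the quantized accessory parameters attached as attribute
#'   `"q_roots"`.
#' @seealso [dense_spectrum_oracle()] for the independent linear-algebra
#'   route, [spectral_decomposition()] for the full fitted object.
#' @export
eigen_spectrum <- function(model) {
  srec <- .as_srec(model)
  q <- .quant_roots(srec)
  lam <- sort(srec$lambda_of_q(q))
  mx <- max(abs(lam))
  if (min(abs(lam)) < 1e-10 * mx) lam[which.min(abs(lam))] <- 0
  else warning("no eigenvalue within snapping tolerance of 0; ",
               "check the model definition")
  if (any(diff(lam) < 1e-8 * mx))
    warning("(near-)repeated eigenvalues detected; spectral projection ",
            "may be unreliable, dense fallback recommended")
  structure(lam, q_roots = q)
}

#' Dense eigenvalue oracle for a birth-death generator
#'
#' Decay rates of the `(N+1) x (N+1)` tridiagonal generator, computed by a
#' symmetrizing similarity transform (off-diagonals
#' \eqn{\sqrt{b_n d_{n+1}}}, a consequence of detailed balance) and a
#' symmetric eigensolver, so the spectrum is provably real.  A vanishing
#' interior rate breaks the transform; the function then falls back to the
#' general eigensolver with a warning.
#'
#' @param g a [birth_death_generator()].
#' @return Sorted decay rates (negated generator eigenvalues).
#' @export
dense_spectrum_oracle <- function(g) {
  stopifnot(inherits(g, "birth_death_generator"))
  N <- g$N
  b <- g$birth; d <- g$death
  if (any(b[1:N] <= 0) || any(d[2:(N + 1L)] <= 0)) {
    warning("zero interior rate: falling back to the general eigensolver")
    return(sort(-Re(eigen(as.matrix(g), only.values = TRUE)$values)))
  }
  off <- sqrt(b[1:N] * d[2:(N + 1L)])
  TT <- diag(-(b + d), N + 1L)
  TT[cbind(1:N, 2:(N + 1L))] <- off
  TT[cbind(2:(N + 1L), 1:N)] <- off
  ev <- eigen(TT, symmetric = TRUE, only.values = TRUE)$values
  sort(-ev)
}

#' Eigenvector of a choice model from its series solution
#'
#' Computes the probability-basis eigenvector \eqn{C(n)}, `n = 0..N`, at a
#' decay rate `lam` by solving the model's three-term recurrence with the
#' closed-form / forward-substitution machinery.  For the binary-choice
#' model these are the Heun series coefficients at \eqn{q(\lambda)} (the
#' generating function is literally \eqn{\sum_n P(n) z^n}); for the
#' vacillating voter model the master-equation rows are used directly.
#' The truncation condition is enforced: if the implied \eqn{C_{N+1}}
#' residual exceeds `tol` (relative), `lam` is rejected as not an
#' eigenvalue.  The zero mode is normalized to sum 1; decaying modes to
#' unit Euclidean norm (their entries sum to 0 automatically).
#'
#' @param model a choice model.
#' @param lam a decay rate from the spectrum.
#' @param tol relative tolerance on the truncation residual.
#' @return Numeric vector of length `N + 1`.
#' @export
eigenvectors_from_series <- function(model, lam, tol = 1e-6) {
  N <- model$N
  if (inherits(model, "binary_choice_model")) {
    srec <- spectral_recurrence(model)
    q <- srec$q_of_lambda(lam)
    rec <- srec$rec
    C <- forward_substitution(rec, N, x = q)
    tail_num <- (ttr_coef(rec, N, "Qt") + q) * C[N + 1L] -
      ttr_coef(rec, N, "P") * C[N]
    scale <- max(abs(C)) * max(1, abs(ttr_coef(rec, N, "Qt") + q))
  } else {
    g <- generator(model)
    b <- g$birth; d <- g$death
    rec <- three_term_recurrence(
      P = function(j) if (j >= 1) b[j] else 0,
      Qt = function(j) b[j + 1L] + d[j + 1L] - lam,
      R = function(j) d[j + 2L])
    C <- forward_substitution(rec, N)
    tail_num <- (b[N + 1L] + d[N + 1L] - lam) * C[N + 1L] - b[N] * C[N]
    scale <- max(abs(C)) * max(1, abs(b[N + 1L] + d[N + 1L] - lam))
  }
  if (abs(tail_num) > tol * scale)
    stop("not an eigenvalue: truncation residual ",
         format(abs(tail_num) / scale), " exceeds tolerance at lambda = ",
         format(lam), call. = FALSE)
  if (abs(lam) <= 1e-8 * max(1, abs(lam))) {
    C / sum(C)
  } else {
    C <- C / sqrt(sum(C^2))
    if (C[which.max(abs(C))] < 0) C <- -C
    C
  }
}

# symmetrized eigendecomposition of a generator; NULL if not applicable
.sym_eigen <- function(g) {
  N <- g$N
  b <- g$birth; d <- g$death
  if (any(b[1:N] <= 0) || any(d[2:(N + 1L)] <= 0)) return(NULL)
  pi_ <- stationary_distribution(g)
  off <- sqrt(b[1:N] * d[2:(N + 1L)])
  TT <- diag(-(b + d), N + 1L)
  TT[cbind(1:N, 2:(N + 1L))] <- off
  TT[cbind(2:(N + 1L), 1:N)] <- off
  es <- eigen(TT, symmetric = TRUE)
  list(lam = -es$values, U = es$vectors, sqrtpi = sqrt(pi_))
}

#' Spectral time evolution of the probability distribution
#'
#' Propagates an initial distribution through
#' \eqn{P(n, t) = \sum_i w_i C_i(n) e^{-\lambda_i t}}, the weights solving
#' \eqn{V w = P(\cdot, 0)}.  Numerically this uses the detailed-balance
#' symmetrization of the generator, so the eigenbasis is orthogonal and
#' the solve is exact; if the symmetrization is unavailable or too
#' ill-conditioned (stationary probabilities spanning more than ~24
#' decades) the dense matrix exponential is used instead, with a warning.
#'
#' @param model a choice model, [birth_death_generator()], or
#'   [spectral_decomposition()] object.
#' @param P0 initial probability vector over `0..N` (nonnegative, sums
#'   to 1).
#' @param times nonnegative times at which to report.
#' @return Matrix with `N + 1` rows and `length(times)` columns; every
#'   column is a probability vector.
#' @export
evolve <- function(model, P0, times) {
  g <- if (inherits(model, "birth_death_generator")) model
       else if (inherits(model, "ctmc_spectrum")) model$generator
       else generator(model)
  stopifnot(length(P0) == g$N + 1L, all(P0 >= 0))
  if (abs(sum(P0) - 1) > 1e-8) stop("P0 must sum to 1")
  if (any(times < 0)) stop("times must be nonnegative")
  se <- .sym_eigen(g)
  cond_ok <- !is.null(se) &&
    (max(se$sqrtpi) / min(se$sqrtpi))^2 < 1e12
  if (!cond_ok) {
    warning("symmetrized eigenbasis unavailable or ill-conditioned; ",
            "falling back to the dense matrix exponential")
    out <- vapply(times, function(t) matrix_exponential_oracle(g, P0, t),
                  numeric(g$N + 1L))
    return(matrix(out, nrow = g$N + 1L,
                  dimnames = list(n = 0:g$N, t = signif(times, 6))))
  }
  w <- crossprod(se$U, P0 / se$sqrtpi)    # U' D P0
  out <- vapply(times, function(t) {
    as.numeric(se$sqrtpi * (se$U %*% (exp(-se$lam * t) * w)))
  }, numeric(g$N + 1L))
  matrix(out, nrow = g$N + 1L, dimnames = list(n = 0:g$N, t = signif(times, 6)))
}

#' Matrix-exponential reference solution
#'
#' Dense \eqn{e^{At} P_0} through [Matrix::expm()]; the reference
#' implementation against which the spectral propagation is validated.
#' No spectral shortcuts.
#'
#' @param g a [birth_death_generator()].
#' @param P0 initial probability vector.
#' @param t a single nonnegative time.
#' @return Probability vector at time `t`.
#' @export
matrix_exponential_oracle <- function(g, P0, t) {
  A <- as.matrix(g)
  as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(A * t))) %*% P0)
}

#' Relaxation-time table
#'
#' Tabulates the nonzero decay rates and their reciprocal relaxation
#' times, flagging the dominant (slowest) mode.
#'
#' @param spectrum a numeric vector of decay rates (e.g. from
#'   [eigen_spectrum()]) or a [spectral_decomposition()] object.
#' @return Data frame with columns `i`, `lambda`, `relaxation_time`,
#'   `dominant`.
#' @export
relaxation_report <- function(spectrum) {
  lam <- if (inherits(spectrum, "ctmc_spectrum")) spectrum$decay_rates
         else as.numeric(spectrum)
  lam <- sort(lam)
  nz <- lam[lam > 0]
  data.frame(i = seq_along(nz), lambda = nz, relaxation_time = 1 / nz,
             dominant = seq_along(nz) == 1L)
}
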