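# Finite continued-fraction (ladder) solution of the spectral recurrence
#   R_j S_j + (lam - Qt_j) + P_j / S_{j-1} = 0,  S_j = C~_{j+1}/C~_j,
# iterated backward from the truncation S_N = 0, and the rational-fraction
# identity linking the ladder to the orthogonal polynomials.

#' Backward continued-fraction ladder
#'
#' Computes \eqn{S_j = \tilde{C}_{j+1}/\tilde{C}_j} for `j = 0..N` by the
#' backward recursion
#' \eqn{S_j = -P_{j+1} / ((\lambda - \tilde{Q}_{j+1}) + R_{j+1} S_{j+1})}
#' from \eqn{S_N = 0}, so that
#' \eqn{S_{N-1} = -P_N / (\lambda - \tilde{Q}_N)}.  A vanishing denominator
#' (\eqn{\lambda} on a resonance of the truncated ladder) is an error
#' carrying the failing index; an interior \eqn{S_j = 0} flags a degenerate
#' ladder with a warning.
#'
#' @param rec a [three_term_recurrence()] object (double mode).
#' @param lam spectral parameter \eqn{\lambda}.
#' @param N truncation index (`N >= 1`).
#' @return Object of class `"cf_ladder"`: list with `N`, `lam`, and `S`
#'   (values \eqn{S_0..S_N}).
#' @export
backward_ladder <- function(rec, lam, N) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 1)
    stop("backward_ladder: N must be a positive integer")
  S <- numeric(N + 1L)
  S[N + 1L] <- 0
  for (j in seq(N - 1L, 0L)) {
    den <- lam - ttr_coef(rec, j + 1L, "Qt")
    # R_{j+1} multiplies S_{j+1}; at the truncation rung S_N = 0 the row
    # coefficient R_N is never needed (finite tables may not define it)
    if (S[j + 2L] != 0) den <- den + ttr_coef(rec, j + 1L, "R") * S[j + 2L]
    if (den == 0)
      stop("continued-fraction pole at j = ", j,
           " (lambda sits on a resonance of the truncated ladder)", call. = FALSE)
    S[j + 1L] <- -ttr_coef(rec, j + 1L, "P") / den
  }
  if (N >= 2L && any(S[seq_len(N - 1L)] == 0))
    warning("degenerate ladder: S_j = 0 at j = ",
            paste(which(S[seq_len(N - 1L)] == 0) - 1L, collapse = ", "))
  structure(list(N = N, lam = lam, S = S), class = "cf_ladder")
}

#' @export
print.cf_ladder <- function(x, ...) {
  cat("<continued-fraction ladder>  N =", x$N, " lambda =", format(x$lam), "\n")
  print(x$S)
  invisible(x)
}

#' Recover recurrence coefficients from a ladder
#'
#' \eqn{\tilde{C}_j = \tilde{C}_0 \prod_{i=0}^{j-1} S_i} for
#' `j = 0..N+1`; the final member is 0 by construction of the truncation.
#'
#' @param ladder a [backward_ladder()] result.
#' @param C0 value of \eqn{\tilde{C}_0} (default 1).
#' @return Numeric vector of length `N + 2`.
#' @export
coefficients_from_ladder <- function(ladder, C0 = 1) {
  stopifnot(inherits(ladder, "cf_ladder"))
  C0 * cumprod(c(1, ladder$S))
}

#' Write a ladder as TSV
#' @param ladder a [backward_ladder()] result.
#' @param file path to write to.
#' @export
write_ladder_tsv <- function(ladder, file) {
  utils::write.table(data.frame(j = 0:ladder$N, S = ladder$S), file = file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Gap of the continued-fraction / orthogonal-polynomial identity
#'
#' For a family given through its accessory-free coefficients
#' (\eqn{\tilde{Q}_j = Q_j + q}), the finite continued fraction
#' \deqn{1/(Q_1 + q - R_1 P_2 / (Q_2 + q - \cdots R_{N-1} P_N / (Q_N + q)))}
#' equals the rational fraction \eqn{\phi_{N-1}^N(q) / \phi_N^N(q)}.  This
#' function evaluates both sides and returns the absolute difference, which
#' is zero up to rounding (exactly zero in exact mode) whenever both sides
#' are defined.  Poles of either side raise an error.
#'
#' @param rec a [three_term_recurrence()] whose `Qt` holds the
#'   \eqn{Q_j} (without the accessory shift).
#' @param q accessory parameter; in exact mode an integer or `c(num, den)`.
#' @param N depth (`N >= 2`).
#' @return Absolute gap (double; exactly 0 when exact arithmetic proves
#'   equality).
#' @export
rational_identity_gap <- function(rec, q, N) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 2)
    stop("rational_identity_gap: N must be >= 2")
  if (rec$mode == "exact") {
    uv <- .x_as_rat(q)
    qq <- eq_new(uv[1], uv[2])
    row <- .ttr_row_int(rec, N)
    t <- eq_add(eq_new(row[["Qt"]], 1), qq)
    for (k in seq(N - 1L, 1L)) {
      if (eq_is_zero(t)) stop("pole in the continued fraction at depth k = ", k, call. = FALSE)
      rowk <- .ttr_row_int(rec, k)
      pk1 <- .ttr_row_int(rec, k + 1L)[["P"]]
      t <- eq_sub(eq_add(eq_new(rowk[["Qt"]], 1), qq),
                  eq_div(eq_new(rowk[["R"]] * pk1, 1), t))
    }
    if (eq_is_zero(t)) stop("pole in the continued fraction at depth k = 0", call. = FALSE)
    lhs <- eq_div(eq_new(1, 1), t)
    pair <- .phi_pair_exact(rec, N, uv[1], uv[2])
    if (bi_is_zero(pair$top)) stop("pole: phi_N^N(q) = 0", call. = FALSE)
    rhs <- eq_new(bi_mul_small(pair$prev, uv[2]), pair$top)
    if (eq_equal(lhs, rhs)) return(0)
    return(abs(as.numeric(eq_sub(lhs, rhs))))
  }
  t <- ttr_coef(rec, N, "Qt") + q
  for (k in seq(N - 1L, 1L)) {
    if (t == 0) stop("pole in the continued fraction at depth k = ", k, call. = FALSE)
    t <- (ttr_coef(rec, k, "Qt") + q) -
      ttr_coef(rec, k, "R") * ttr_coef(rec, k + 1L, "P") / t
  }
  if (t == 0) stop("pole in the continued fraction at depth k = 0", call. = FALSE)
  lhs <- 1 / t
  ph <- phi_family(rec, N, q)$values
  if (ph[N + 1L] == 0) stop("pole: phi_N^N(q) = 0", call. = FALSE)
  rhs <- ph[N] / ph[N + 1L]
  abs(lhs - rhs)
}
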