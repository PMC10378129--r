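# Closed-form solution of the three-term recurrence:
#   C_i = [ Qt_0 phi_{i-1}^{i-1}(0) - R_0 P_1 phi_{i-2}^{i-1}(0) ] / prod_{j<i} R_j
# (phi_{-1} = 0 by convention, so C_1 = Qt_0 / R_0), together with the
# forward-substitution oracle and the tridiagonal inverse-column elements.

# rational x spec -> c(u, v)
.x_as_rat <- function(x) {
  if (length(x) == 1L) {
    if (x != round(x)) stop("exact mode requires integer or c(num, den) rational x")
    c(x, 1)
  } else c(x[1], x[2])
}

# signed log2-product of R_0..R_{i-1}; errors on zero
.R_prod_log2 <- function(rec, i, from = 0L) {
  s <- 1; lg <- 0
  if (i - 1L >= from) for (j in from:(i - 1L)) {
    r <- ttr_coef(rec, j, "R")
    if (r == 0) stop("singular recurrence: R_", j, " = 0", call. = FALSE)
    s <- s * sign(r); lg <- lg + log2(abs(r))
  }
  list(sign = s, log2 = lg)
}

.R_prod_exact <- function(rec, i, from = 0L) {
  acc <- bi(1)
  if (i - 1L >= from) for (j in from:(i - 1L)) {
    r <- .ttr_row_int(rec, j)[["R"]]
    if (r == 0) stop("singular recurrence: R_", j, " = 0", call. = FALSE)
    acc <- bi_mul_small(acc, r)
  }
  acc
}

.sig_exp_to_num <- function(sig, lg2) {
  # sig * 2^lg2 as a double, warning instead of silently overflowing
  if (sig == 0) return(0)
  if (lg2 > 1023) { warning("closed-form value overflows double; returning Inf"); return(sign(sig) * Inf) }
  sign(sig) * 2^(lg2 + log2(abs(sig)))
}

#' Closed-form value of a three-term recurrence solution
#'
#' Evaluates the solution member \eqn{C_i} of the recurrence directly from
#' the orthogonal-polynomial closed form, without computing
#' \eqn{C_1,\dots,C_{i-1}}.  With `x` nonzero the family's \eqn{\tilde{Q}_j}
#' are all shifted by `x` (the Heun accessory-parameter convention, where
#' \eqn{\tilde{Q}_j = Q_j + q} and the polynomials are evaluated at
#' \eqn{x = q}).
#'
#' In exact mode the result is an exact rational (class `"ttr_fraction"`);
#' `x` may then be an integer or a rational pair `c(num, den)`.
#'
#' @param rec a [three_term_recurrence()] object.
#' @param i index (`i >= 0`).
#' @param x uniform shift added to every \eqn{\tilde{Q}_j} (default 0).
#' @return A double, or a `"ttr_fraction"` in exact mode.
#' @seealso [forward_substitution()] for the row-by-row oracle.
#' @examples
#' rec <- three_term_recurrence(function(j) 1, function(j) 2, function(j) 1)
#' closed_form_C(rec, 3)   # 4
#' @export
closed_form_C <- function(rec, i, x = 0) {
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 0)
    stop("closed_form_C: i must be a nonnegative integer")
  exact <- rec$mode == "exact"
  if (i == 0L) return(if (exact) eq_new(1, 1) else 1)

  if (exact) {
    uv <- .x_as_rat(x); u <- uv[1]; v <- uv[2]
    pair <- .phi_pair_exact(rec, i - 1L, u, v)
    row0 <- .ttr_row_int(rec, 0L)
    p1 <- if (i >= 2L) .ttr_row_int(rec, 1L)[["P"]] else 0
    t1 <- bi_add(bi_mul_small(pair$top, row0[["Qt"]] * v), bi_mul_small(pair$top, u))
    t2 <- bi_mul_small(bi_mul_small(bi_mul_small(pair$prev, v * v), row0[["R"]]), p1)
    num <- bi_sub(t1, t2)
    den <- .R_prod_exact(rec, i)
    vpow <- bi(1)
    for (k in seq_len(i)) vpow <- bi_mul_small(vpow, v)
    return(eq_new(num, bi_mul(den, vpow)))
  }

  pair <- .phi_pair_scaled(rec, i - 1L, x)
  qt0 <- ttr_coef(rec, 0L, "Qt") + x
  r0p1 <- if (i >= 2L) ttr_coef(rec, 0L, "R") * ttr_coef(rec, 1L, "P") else 0
  combo <- qt0 * pair$top - r0p1 * pair$prev
  scale_mag <- max(abs(qt0 * pair$top), abs(r0p1 * pair$prev))
  if (i > 25L && scale_mag > 0 && abs(combo) < 1e-10 * scale_mag)
    warning("severe cancellation in the closed form at i = ", i,
            "; consider exact mode for rational coefficients")
  pr <- .R_prod_log2(rec, i)
  if (combo == 0) return(0)
  .sig_exp_to_num(sign(combo) * pr$sign,
                  log2(abs(combo)) + pair$e2 - pr$log2)
}

#' Solve a three-term recurrence by forward substitution
#'
#' The brute-force oracle: iterates
#' \eqn{C_{j+1} = (\tilde{Q}_j C_j - P_j C_{j-1}) / R_j} from the boundary
#' conditions.  Algebraically identical to [closed_form_C()]; in exact mode
#' the two agree exactly, which is the package's central self-check.
#'
#' @inheritParams closed_form_C
#' @param i_max last index to compute.
#' @return Numeric vector `C_0..C_{i_max}`, or a list of `"ttr_fraction"`
#'   in exact mode.
#' @export
forward_substitution <- function(rec, i_max, x = 0) {
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max != round(i_max) || i_max < 0)
    stop("forward_substitution: i_max must be a nonnegative integer")
  exact <- rec$mode == "exact"

  if (exact) {
    uv <- .x_as_rat(x); u <- uv[1]; v <- uv[2]
    # W_j = C_j v^j prod_{k<j} R_k:  W_{j+1} = (Qt_j v + u) W_j - P_j v^2 R_{j-1} W_{j-1}
    W <- vector("list", i_max + 1L)
    W[[1L]] <- bi(1)
    Wm1 <- bi(0)
    if (i_max >= 1L) for (j in 0L:(i_max - 1L)) {
      row <- .ttr_row_int(rec, j)
      if (row[["R"]] == 0) stop("singular recurrence: R_", j, " = 0", call. = FALSE)
      t1 <- bi_add(bi_mul_small(W[[j + 1L]], row[["Qt"]] * v),
                   bi_mul_small(W[[j + 1L]], u))
      prevW <- if (j >= 1L) W[[j]] else Wm1
      rfac <- if (j >= 1L) .ttr_row_int(rec, j - 1L)[["R"]] else 0
      t2 <- bi_mul_small(bi_mul_small(bi_mul_small(prevW, v * v), row[["P"]]), rfac)
      W[[j + 2L]] <- bi_sub(t1, t2)
    }
    den <- bi(1)
    out <- vector("list", i_max + 1L)
    out[[1L]] <- eq_new(1, 1)
    if (i_max >= 1L) for (j in 1L:i_max) {
      den <- bi_mul_small(bi_mul_small(den, .ttr_row_int(rec, j - 1L)[["R"]]), v)
      out[[j + 1L]] <- eq_new(W[[j + 1L]], den)
    }
    return(out)
  }

  C <- numeric(i_max + 1L)
  C[1L] <- 1
  Cm1 <- 0
  if (i_max >= 1L) for (j in 0L:(i_max - 1L)) {
    row <- .ttr_row_dbl(rec, j)
    if (row[["R"]] == 0) stop("singular recurrence: R_", j, " = 0", call. = FALSE)
    prevC <- if (j >= 1L) C[j] else Cm1
    C[j + 2L] <- ((row[["Qt"]] + x) * C[j + 1L] - row[["P"]] * prevC) / row[["R"]]
    if (!is.finite(C[j + 2L]))
      stop("forward substitution overflowed at j = ", j + 1L, "; use exact mode")
  }
  C
}

#' First- and second-column elements of the tridiagonal inverse
#'
#' Returns \eqn{\theta_{i,1} = \phi_{i-1}^{i-1}(0) / \prod_{j=0}^{i-1} R_j}
#' and \eqn{\theta_{i,2} = \phi_{i-2}^{i-1}(0) / \prod_{j=1}^{i-1} R_j},
#' the only inverse elements the closed form needs:
#' \eqn{C_i = \tilde{Q}_0 \theta_{i,1} - P_1 \theta_{i,2}}.  The infinite
#' determinant behind them is never evaluated; only these cancelled
#' quotients are.
#'
#' @inheritParams closed_form_C
#' @param i row index, `i >= 1`.
#' @return List of class `"inverse_column_elements"` with `i`, `theta1`,
#'   `theta2` (doubles, or `"ttr_fraction"` in exact mode).
#' @export
inverse_column_elements <- function(rec, i) {
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 1)
    stop("inverse_column_elements: i must be >= 1 (no inverse row at i = 0)")
  exact <- rec$mode == "exact"
  if (exact) {
    pair <- .phi_pair_exact(rec, i - 1L, 0, 1)
    th1 <- eq_new(pair$top, .R_prod_exact(rec, i))
    th2 <- if (i >= 2L) eq_new(pair$prev, .R_prod_exact(rec, i, from = 1L))
           else eq_new(0, 1)
    return(structure(list(i = i, theta1 = th1, theta2 = th2),
                     class = "inverse_column_elements"))
  }
  pair <- .phi_pair_scaled(rec, i - 1L, 0)
  pr1 <- .R_prod_log2(rec, i)
  th1 <- if (pair$top == 0) 0 else
    .sig_exp_to_num(sign(pair$top) * pr1$sign, log2(abs(pair$top)) + pair$e2 - pr1$log2)
  th2 <- 0
  if (i >= 2L && pair$prev != 0) {
    pr2 <- .R_prod_log2(rec, i, from = 1L)
    th2 <- .sig_exp_to_num(sign(pair$prev) * pr2$sign,
                           log2(abs(pair$prev)) + pair$e2 - pr2$log2)
  }
  structure(list(i = i, theta1 = th1, theta2 = th2),
            class = "inverse_column_elements")
}

#' @export
print.inverse_column_elements <- function(x, ...) {
  f <- function(v) if (inherits(v, "ttr_fraction")) as.character(v) else format(v)
  cat("<inverse column elements>  i =", x$i,
      "\n  theta_{i,1} =", f(x$theta1), "\n  theta_{i,2} =", f(x$theta2), "\n")
  invisible(x)
}
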