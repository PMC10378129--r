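# The recursively defined orthogonal polynomials phi_j^i(x):
#   phi_0^i(x) = 1,  phi_1^i(x) = x + Qt_i,
#   phi_j^i(x) = (Qt_{i-(j-1)} + x) phi_{j-1}^i(x)
#                - R_{i-(j-1)} P_{i-(j-2)} phi_{j-2}^i(x),  j = 2..i.
# They express the determinant and leading minors of the tridiagonal matrix
# behind the recurrence; the closed form for C_i is built from phi at x = 0,
# the Heun series coefficients from phi at the accessory parameter x = q.

#' Evaluate the orthogonal polynomial family behind a recurrence
#'
#' Computes \eqn{\phi_j^i(x)} for `j = 0..i`, the monic degree-`j`
#' polynomials whose recursion mirrors the recurrence rows in reverse order.
#' With `x = NULL` the polynomials are returned symbolically as coefficient
#' vectors (ascending powers) instead of values.
#'
#' @param rec a [three_term_recurrence()] object.
#' @param i superscript index (the family has `i + 1` members).
#' @param x evaluation point, or `NULL` for symbolic coefficient vectors.
#' @return For numeric `x`: an object of class `"phi_family"` with fields
#'   `i`, `x`, `values` (\eqn{\phi_0^i(x), \ldots, \phi_i^i(x)}).  For
#'   `x = NULL`: a list of `i + 1` coefficient vectors.
#' @examples
#' rec <- three_term_recurrence(function(j) 1, function(j) 2, function(j) 1)
#' phi_family(rec, 2, 0)$values   # 1, 2, 3
#' @export
phi_family <- function(rec, i, x = 0) {
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 0)
    stop("phi_family: i must be a nonnegative integer")
  if (is.null(x)) return(.phi_all_poly(rec, i))
  vals <- numeric(i + 1L)
  vals[1L] <- 1
  if (i >= 1L) vals[2L] <- x + ttr_coef(rec, i, "Qt")
  if (i >= 2L) {
    for (j in 2L:i) {
      k <- i - (j - 1L)
      vals[j + 1L] <- (ttr_coef(rec, k, "Qt") + x) * vals[j] -
        ttr_coef(rec, k, "R") * ttr_coef(rec, k + 1L, "P") * vals[j - 1L]
    }
  }
  structure(list(i = i, x = x, values = vals), class = "phi_family")
}

#' @export
print.phi_family <- function(x, ...) {
  cat("<phi family>  i =", x$i, " at x =", format(x$x), "\n")
  print(x$values)
  invisible(x)
}

# symbolic phi_j^i as coefficient vectors (ascending powers of x)
.phi_all_poly <- function(rec, i) {
  out <- vector("list", i + 1L)
  out[[1L]] <- 1
  if (i >= 1L) out[[2L]] <- c(ttr_coef(rec, i, "Qt"), 1)
  if (i >= 2L) {
    for (j in 2L:i) {
      k <- i - (j - 1L)
      p1 <- out[[j]]
      # (x + Qt_k) * p1
      a <- c(0, p1) + c(ttr_coef(rec, k, "Qt") * p1, 0)
      cc <- ttr_coef(rec, k, "R") * ttr_coef(rec, k + 1L, "P")
      p2 <- out[[j - 1L]]
      a[seq_along(p2)] <- a[seq_along(p2)] - cc * p2
      out[[j + 1L]] <- a
    }
  }
  out
}

# last two members (phi_i^i, phi_{i-1}^i) at x, with power-of-two
# renormalization; returns list(top, prev, e2) where true values are
# top * 2^e2, prev * 2^e2.
.phi_pair_scaled <- function(rec, i, x) {
  prev <- 0; top <- 1; e2 <- 0
  if (i >= 1L) { prev <- 1; top <- x + ttr_coef(rec, i, "Qt") }
  if (i >= 2L) {
    for (j in 2L:i) {
      k <- i - (j - 1L)
      new <- (ttr_coef(rec, k, "Qt") + x) * top -
        ttr_coef(rec, k, "R") * ttr_coef(rec, k + 1L, "P") * prev
      prev <- top; top <- new
      mx <- max(abs(top), abs(prev))
      if (is.finite(mx) && mx > 1e200) {
        s <- 2^(-680L)             # 2^680 ~ 5e204
        top <- top * s; prev <- prev * s; e2 <- e2 + 680L
      }
      if (!is.finite(top)) stop("phi recursion overflow at j = ", j,
                                "; use exact mode")
    }
  }
  list(top = top, prev = prev, e2 = e2)
}

# exact integer pair psi_j = v^j phi_j^i(u/v) for x = u/v (cleared rows):
#   psi_j = (Qt_k v + u) psi_{j-1} - v^2 R_k P_{k+1} psi_{j-2}
.phi_pair_exact <- function(rec, i, u = 0, v = 1) {
  prev <- bi(0); top <- bi(1)
  if (i >= 1L) {
    prev <- bi(1)
    top <- bi(.ttr_row_int(rec, i)[["Qt"]] * v + u)
  }
  if (i >= 2L) {
    for (j in 2L:i) {
      k <- i - (j - 1L)
      rowk <- .ttr_row_int(rec, k)
      pk1 <- .ttr_row_int(rec, k + 1L)[["P"]]
      t1 <- bi_add(bi_mul_small(top, rowk[["Qt"]] * v), bi_mul_small(top, u))
      t2 <- bi_mul_small(bi_mul_small(bi_mul_small(prev, v * v), rowk[["R"]]), pk1)
      new <- bi_sub(t1, t2)
      prev <- top; top <- new
    }
  }
  list(top = top, prev = prev)
}
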