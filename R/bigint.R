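# Exact big-integer arithmetic (pure R), the backbone of the exact tier.
#
# A big integer is list(s = sign in {-1,0,1}, m = numeric limb vector,
# little-endian, base 1e6).  Limb products stay below 2^53 for operand
# lengths up to ~9000 limbs, far beyond anything the recurrences produce.
# Only +, -, * and comparison are ever needed: the closed form and the
# forward-substitution oracle are made division-free by clearing row
# denominators and tracking the common denominator prod(R_j) separately.

.BI_BASE <- 1e6
.BI_DIGITS <- 6L

.bi_carry <- function(m) {
  repeat {
    q <- floor(m / .BI_BASE)
    if (!any(q != 0)) break
    m <- m - q * .BI_BASE
    m <- c(m, 0)
    m[-1] <- m[-1] + q
  }
  while (length(m) > 1L && m[length(m)] == 0) m <- m[-length(m)]
  m
}

bi <- function(x) {
  if (is.list(x) && !is.null(x$s)) return(x)
  stopifnot(length(x) == 1L, is.finite(x), x == round(x), abs(x) < 2^53)
  s <- sign(x)
  x <- abs(x)
  if (x == 0) return(list(s = 0, m = 0))
  m <- numeric(0)
  while (x > 0) {
    m <- c(m, x %% .BI_BASE)
    x <- (x - x %% .BI_BASE) / .BI_BASE
  }
  list(s = s, m = m)
}

bi_is_zero <- function(a) a$s == 0

.bi_cmp_mag <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(as.integer(sign(la - lb)))
  for (k in seq(la, 1L)) {
    if (a[k] != b[k]) return(as.integer(sign(a[k] - b[k])))
  }
  0L
}

bi_cmp <- function(a, b) {
  if (a$s != b$s) return(as.integer(sign(a$s - b$s)))
  if (a$s == 0) return(0L)
  as.integer(a$s * .bi_cmp_mag(a$m, b$m))
}

.bi_add_mag <- function(a, b) {
  n <- max(length(a), length(b))
  m <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  .bi_carry(m)
}

# |a| - |b| assuming |a| >= |b|
.bi_sub_mag <- function(a, b) {
  m <- c(a, numeric(0)) - c(b, numeric(length(a) - length(b)))
  # borrow
  repeat {
    neg <- which(m < 0)
    if (!length(neg)) break
    m[neg] <- m[neg] + .BI_BASE
    m[neg + 1L] <- m[neg + 1L] - 1
  }
  while (length(m) > 1L && m[length(m)] == 0) m <- m[-length(m)]
  m
}

bi_neg <- function(a) list(s = -a$s, m = a$m)

bi_add <- function(a, b) {
  if (a$s == 0) return(b)
  if (b$s == 0) return(a)
  if (a$s == b$s) return(list(s = a$s, m = .bi_add_mag(a$m, b$m)))
  cm <- .bi_cmp_mag(a$m, b$m)
  if (cm == 0) return(list(s = 0, m = 0))
  if (cm > 0) list(s = a$s, m = .bi_sub_mag(a$m, b$m))
  else        list(s = b$s, m = .bi_sub_mag(b$m, a$m))
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$s == 0 || b$s == 0) return(list(s = 0, m = 0))
  x <- a$m; y <- b$m
  if (length(x) > length(y)) { t <- x; x <- y; y <- t }
  r <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x)) {
    idx <- i:(i + length(y) - 1L)
    r[idx] <- r[idx] + x[i] * y
    if (i %% 64L == 0L) r <- .bi_carry(r)   # keep partial sums < 2^53
  }
  list(s = a$s * b$s, m = .bi_carry(r))
}

# multiply by a machine integer k (|k| < ~9e9/base of safety); split if large
bi_mul_small <- function(a, k) {
  stopifnot(k == round(k))
  if (k == 0 || a$s == 0) return(list(s = 0, m = 0))
  if (abs(k) >= 1e7) return(bi_mul(a, bi(k)))
  list(s = a$s * sign(k), m = .bi_carry(a$m * abs(k)))
}

bi_to_str <- function(a) {
  if (a$s == 0) return("0")
  n <- length(a$m)
  parts <- vapply(seq(n, 1L), function(k) {
    if (k == n) format(a$m[k], scientific = FALSE)
    else formatC(a$m[k], width = .BI_DIGITS, flag = "0", format = "d")
  }, character(1))
  paste0(if (a$s < 0) "-" else "", paste(parts, collapse = ""))
}

# double approximation of a (may overflow to +-Inf)
bi_to_double <- function(a) {
  if (a$s == 0) return(0)
  n <- length(a$m)
  top <- 0
  for (k in seq(n, max(1L, n - 2L))) top <- top * .BI_BASE + a$m[k]
  e <- max(0L, n - 3L)
  a$s * top * .BI_BASE^e
}

# double approximation of num/den with exponent bookkeeping, robust to
# individual overflow of either operand
bi_ratio <- function(num, den) {
  if (bi_is_zero(den)) stop("bigint ratio: zero denominator")
  if (bi_is_zero(num)) return(0)
  tops <- function(a) {
    n <- length(a$m)
    top <- 0
    for (k in seq(n, max(1L, n - 2L))) top <- top * .BI_BASE + a$m[k]
    list(top = top, e = max(0L, n - 3L))
  }
  a <- tops(num); b <- tops(den)
  r <- (num$s * a$top) / (den$s * b$top)
  de <- (a$e - b$e) * log2(.BI_BASE)
  r * 2^de
}

# ---- exact rationals (unreduced; equality via cross-multiplication) ----

eq_new <- function(num, den) {
  num <- bi(num); den <- bi(den)
  if (bi_is_zero(den)) stop("exact rational with zero denominator")
  if (den$s < 0) { num <- bi_neg(num); den <- bi_neg(den) }
  structure(list(num = num, den = den), class = "ttr_fraction")
}

#' Exact equality of two exact rationals
#'
#' Cross-multiplied comparison of two `"ttr_fraction"` values (as returned
#' by [closed_form_C()] and [forward_substitution()] in exact mode); no
#' reduction or rounding is involved.
#'
#' @param a,b `"ttr_fraction"` objects.
#' @return `TRUE` or `FALSE`.
#' @export
eq_equal <- function(a, b) {
  bi_cmp(bi_mul(a$num, b$den), bi_mul(b$num, a$den)) == 0L
}

eq_add <- function(a, b) {
  eq_new(bi_add(bi_mul(a$num, b$den), bi_mul(b$num, a$den)), bi_mul(a$den, b$den))
}

eq_sub <- function(a, b) eq_add(a, eq_new(bi_neg(b$num), b$den))

eq_mul <- function(a, b) eq_new(bi_mul(a$num, b$num), bi_mul(a$den, b$den))

eq_div <- function(a, b) {
  if (bi_is_zero(b$num)) stop("exact rational division by zero")
  eq_new(bi_mul(a$num, b$den), bi_mul(a$den, b$num))
}

eq_is_zero <- function(a) bi_is_zero(a$num)

#' @export
as.double.ttr_fraction <- function(x, ...) bi_ratio(x$num, x$den)

#' @export
as.character.ttr_fraction <- function(x, ...) {
  paste0(bi_to_str(x$num), "/", bi_to_str(x$den))
}

#' @export
format.ttr_fraction <- function(x, ...) as.character(x)

#' @export
print.ttr_fraction <- function(x, ...) {
  cat("<exact rational> ", as.character(x), "\n", sep = "")
  invisible(x)
}
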