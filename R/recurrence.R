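# Three-term recurrence families R_j C_{j+1} - Qt_j C_j + P_j C_{j-1} = 0
# with boundary conditions C_0 = 1, C_{-1} = 0.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
.lcm2 <- function(a, b) a / .gcd2(a, b) * b

# normalize one coefficient spec into a closure j -> c(num, den)
.ttr_family <- function(x, name) {
  if (is.function(x)) {
    function(j) {
      v <- x(j)
      if (length(v) == 1L) c(as.numeric(v), 1) else c(v[1], v[2])
    }
  } else if (is.list(x) && !is.null(x$num)) {
    num <- as.numeric(x$num); den <- as.numeric(x$den)
    if (length(num) != length(den)) stop(name, ": num/den length mismatch")
    if (any(den == 0)) stop(name, ": zero denominator in rational table")
    function(j) {
      if (j < 0 || j >= length(num))
        stop("coefficient table for ", name, " has no entry at index j = ", j,
             " (table covers 0..", length(num) - 1L, ")", call. = FALSE)
      c(num[j + 1L], den[j + 1L])
    }
  } else if (is.numeric(x)) {
    tab <- as.numeric(x)
    function(j) {
      if (j < 0 || j >= length(tab))
        stop("coefficient table for ", name, " has no entry at index j = ", j,
             " (table covers 0..", length(tab) - 1L, ")", call. = FALSE)
      c(tab[j + 1L], 1)
    }
  } else stop(name, " must be a function, numeric table, or list(num=, den=)")
}

#' Define a general three-term recurrence family
#'
#' Represents the recurrence \eqn{R_j C_{j+1} - \tilde{Q}_j C_j + P_j C_{j-1}
#' = 0} for \eqn{j \ge 0}, with the fixed boundary conditions \eqn{C_0 = 1}
#' and \eqn{C_{-1} = 0}.  The coefficient families may be supplied as
#' closed-form rules (functions of the row index `j`), as finite numeric
#' tables indexed from `j = 0`, or as exact rational tables
#' `list(num =, den =)`.  A table shorter than a requested row is an error,
#' never padded.
#'
#' Selected rows can be replaced wholesale through `overrides`, a named list
#' mapping row index (as character) to a list with any of `P`, `Qt`, `R`.
#' Overrides are applied before any downstream evaluation, so the
#' orthogonal-polynomial machinery always sees the effective coefficients
#' (this is how boundary-modified models such as the vacillating voter chain
#' are expressed).
#'
#' In `mode = "exact"` all computations downstream
#' ([closed_form_C()], [forward_substitution()], [inverse_column_elements()])
#' are carried out in exact big-integer arithmetic.  Rational coefficients
#' are cleared row by row (the recurrence is row-homogeneous, so multiplying
#' one row by a common nonzero constant leaves every \eqn{C_i} unchanged);
#' plain numeric coefficients must then be integer-valued.
#'
#' @param P,Qt,R coefficient families (`Qt` is \eqn{\tilde{Q}_j}).
#' @param overrides optional named list of per-row replacements.
#' @param mode `"double"` (default) or `"exact"`.
#' @return An object of class `"ttr"`.
#' @examples
#' rec <- three_term_recurrence(P = function(j) 1, Qt = function(j) 2,
#'                              R = function(j) 1)
#' forward_substitution(rec, 4)   # 1 2 3 4 5
#' @export
three_term_recurrence <- function(P, Qt, R, overrides = NULL,
                                  mode = c("double", "exact")) {
  mode <- match.arg(mode)
  fam <- list(P = .ttr_family(P, "P"), Qt = .ttr_family(Qt, "Qt"),
              R = .ttr_family(R, "R"))
  ov <- list()
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named list, names giving row indices")
    for (nm in names(overrides)) {
      o <- overrides[[nm]]
      o <- o[intersect(names(o), c("P", "Qt", "R"))]
      ov[[nm]] <- lapply(o, function(v) if (length(v) == 1L) c(v, 1) else c(v[1], v[2]))
    }
  }
  structure(list(fam = fam, overrides = ov, mode = mode,
                 cache = new.env(parent = emptyenv())),
            class = "ttr")
}

# rational c(num, den) of one coefficient with overrides applied
.ttr_rat <- function(rec, j, what) {
  key <- as.character(j)
  if (!is.null(rec$overrides[[key]]) && !is.null(rec$overrides[[key]][[what]]))
    return(rec$overrides[[key]][[what]])
  rec$fam[[what]](j)
}

#' Evaluate effective recurrence coefficients
#'
#' Returns the value of \eqn{P_j}, \eqn{\tilde{Q}_j} or \eqn{R_j} after any
#' row overrides, as a double.
#'
#' @param rec a [three_term_recurrence()] object.
#' @param j row index (scalar or vector, `j >= 0`).
#' @param what one of `"P"`, `"Qt"`, `"R"`.
#' @export
ttr_coef <- function(rec, j, what = c("P", "Qt", "R")) {
  what <- match.arg(what)
  vapply(j, function(jj) {
    v <- .ttr_rat(rec, jj, what)
    v[1] / v[2]
  }, numeric(1))
}

# integer-cleared row (exact mode): returns c(P, Qt, R) integral doubles
.ttr_row_int <- function(rec, j) {
  key <- sprintf("r%d", j)
  hit <- rec$cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- .ttr_rat(rec, j, "P"); q <- .ttr_rat(rec, j, "Qt"); r <- .ttr_rat(rec, j, "R")
  for (v in list(p, q, r)) {
    if (v[1] != round(v[1]) || v[2] != round(v[2]))
      stop("exact mode requires integer or rational-table coefficients (row j = ", j, ")")
  }
  L <- .lcm2(.lcm2(abs(p[2]), abs(q[2])), abs(r[2]))
  row <- c(P = p[1] * (L / p[2]), Qt = q[1] * (L / q[2]), R = r[1] * (L / r[2]))
  if (any(abs(row) >= 2^53)) stop("exact mode: cleared coefficient exceeds 2^53 at row ", j)
  rec$cache[[key]] <- row
  row
}

.ttr_row_dbl <- function(rec, j) {
  c(P = ttr_coef(rec, j, "P"), Qt = ttr_coef(rec, j, "Qt"), R = ttr_coef(rec, j, "R"))
}

#' @export
print.ttr <- function(x, ...) {
  cat("<three-term recurrence family>  mode:", x$mode, "\n")
  cat("  R_j C_{j+1} - Qt_j C_j + P_j C_{j-1} = 0,  C_0 = 1, C_{-1} = 0\n")
  jmax <- 4L
  ok <- try({
    tab <- data.frame(j = 0:jmax,
                      P = ttr_coef(x, 0:jmax, "P"),
                      Qt = ttr_coef(x, 0:jmax, "Qt"),
                      R = ttr_coef(x, 0:jmax, "R"))
    print(tab, row.names = FALSE)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) cat("  (coefficient table shorter than 5 rows)\n")
  if (length(x$overrides))
    cat("  row overrides at j =", paste(names(x$overrides), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a recurrence family and its solution
#'
#' @param rec a [three_term_recurrence()] object.
#' @param j_max last row to tabulate.
#' @return A data frame with columns `j`, `P`, `Qt`, `R` and the solution `C`.
#' @export
ttr_table <- function(rec, j_max) {
  C <- forward_substitution(rec, j_max)
  if (rec$mode == "exact") C <- vapply(C, as.numeric, numeric(1))
  data.frame(j = 0:j_max,
             P = ttr_coef(rec, 0:j_max, "P"),
             Qt = ttr_coef(rec, 0:j_max, "Qt"),
             R = ttr_coef(rec, 0:j_max, "R"),
             C = C)
}

#' Write a recurrence table as TSV
#'
#' @param rec a [three_term_recurrence()] object.
#' @param j_max last row.
#' @param file path to write to.
#' @export
write_ttr_tsv <- function(rec, j_max, file) {
  utils::write.table(ttr_table(rec, j_max), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
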