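# General and confluent Heun equations: parameter containers, the
# three-term recurrences their Frobenius coefficients satisfy, closed-form
# series coefficients, guarded series evaluation, and ODE-residual /
# initial-value oracles used to validate the recurrence coefficients.

.check_gamma <- function(gamma) {
  if (abs(gamma - round(gamma)) < 1e-12 && round(gamma) <= 0)
    stop("singular gamma: gamma must not be 0, -1, -2, ... ",
         "(it enters the series denominators)", call. = FALSE)
}

#' General Heun equation parameters
#'
#' Container for the parameter set \eqn{(a, q; \alpha, \beta, \gamma,
#' \delta, \epsilon)} of the general Heun equation
#' \deqn{y'' + \left(\frac{\gamma}{z} + \frac{\delta}{z-1} +
#'   \frac{\epsilon}{z-a}\right) y' + \frac{\alpha\beta z - q}{z(z-1)(z-a)}
#'   y = 0,}
#' with regular singularities at \eqn{0, 1, a, \infty}.  If `epsilon` is
#' omitted it is reconstructed from the Fuchs relation
#' \eqn{\alpha+\beta+1 = \gamma+\delta+\epsilon}; if supplied, the relation
#' is checked.  Only real parameters are supported; the package works with
#' the index-0 Frobenius solution about \eqn{z = 0}, for which
#' \eqn{\gamma} must avoid the non-positive integers.
#'
#' @param a third finite singularity (`a != 0`).
#' @param q accessory parameter.
#' @param alpha,beta,gamma,delta,epsilon exponent parameters.
#' @return Object of class `c("general_heun", "heun_params")`.
#' @export
general_heun <- function(a, q, alpha, beta, gamma, delta, epsilon = NULL) {
  if (a == 0) stop("degenerate singularity: a must be nonzero", call. = FALSE)
  .check_gamma(gamma)
  if (is.null(epsilon)) {
    epsilon <- alpha + beta + 1 - gamma - delta
  } else if (abs(alpha + beta + 1 - gamma - delta - epsilon) > 1e-8) {
    stop("Fuchs relation alpha+beta+1 = gamma+delta+epsilon violated", call. = FALSE)
  }
  structure(list(a = a, q = q, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, epsilon = epsilon),
            class = c("general_heun", "heun_params"))
}

#' Confluent Heun equation parameters
#'
#' Container for \eqn{(q; \alpha, \gamma, \delta, \epsilon)} of the
#' confluent Heun equation
#' \deqn{y'' + \left(\epsilon + \frac{\gamma}{z} + \frac{\delta}{z-1}\right)
#'   y' + \frac{\alpha z + q}{z(z-1)} y = 0,}
#' the \eqn{a \to \infty} confluence of the general equation (regular
#' singularities at 0 and 1, a rank-1 irregular singularity at
#' \eqn{\infty}).  The accessory-parameter sign convention (`+ q` in the
#' numerator) is the one the confluence limit of the general equation
#' produces, so that \eqn{C_1 = q/\gamma} in both equations; see the
#' package vignette.
#'
#' @param q accessory parameter.
#' @param alpha,gamma,delta,epsilon parameters (primes of the confluence
#'   limit dropped).
#' @return Object of class `c("confluent_heun", "heun_params")`.
#' @export
confluent_heun <- function(q, alpha, gamma, delta, epsilon) {
  .check_gamma(gamma)
  structure(list(q = q, alpha = alpha, gamma = gamma, delta = delta,
                 epsilon = epsilon),
            class = c("confluent_heun", "heun_params"))
}

#' @export
print.heun_params <- function(x, ...) {
  kind <- if (inherits(x, "general_heun")) "general" else "confluent"
  cat("<", kind, " Heun parameters>\n", sep = "")
  fields <- unclass(x)
  cat(paste0("  ", names(fields), " = ", vapply(fields, format, character(1))),
      sep = "\n")
  invisible(x)
}

#' Three-term recurrence of a Heun Frobenius solution
#'
#' Builds the recurrence satisfied by the series coefficients of the
#' index-0 Frobenius solution \eqn{y(z) = \sum_j C_j z^j}.  For the general
#' equation the coefficient families are
#' \eqn{P_j = (j-1+\alpha)(j-1+\beta)},
#' \eqn{Q_j = j[(j-1+\gamma)(1+a) + a\delta + \epsilon]},
#' \eqn{R_j = a(j+1)(j+\gamma)}; for the confluent equation
#' \eqn{P_j = (1-j)\epsilon - \alpha}, \eqn{Q_j = j(j-1) + j(\gamma +
#' \delta - \epsilon)}, \eqn{R_j = (j+1)(j+\gamma)}.  Both groupings are
#' pinned down by the ODE-residual oracle ([heun_ode_residual()]): the
#' truncated series built from them satisfies the differential equation to
#' a residual that vanishes with the truncation order.
#'
#' With `include_accessory = TRUE` (default) the returned family carries
#' \eqn{\tilde{Q}_j = Q_j + q}; with `FALSE` it carries the bare
#' \eqn{Q_j}, the form used by [quantization_polynomial()] and
#' [rational_identity_gap()] where the accessory parameter is the
#' polynomial variable.
#'
#' @param params a [general_heun()] or [confluent_heun()] object.
#' @param include_accessory add `q` to every \eqn{Q_j}?
#' @return A [three_term_recurrence()] object.
#' @export
heun_recurrence <- function(params, include_accessory = TRUE) {
  UseMethod("heun_recurrence")
}

#' @export
heun_recurrence.general_heun <- function(params, include_accessory = TRUE) {
  a <- params$a; al <- params$alpha; be <- params$beta
  ga <- params$gamma; de <- params$delta; ep <- params$epsilon
  qq <- if (include_accessory) params$q else 0
  three_term_recurrence(
    P = function(j) (j - 1 + al) * (j - 1 + be),
    Qt = function(j) j * ((j - 1 + ga) * (1 + a) + a * de + ep) + qq,
    R = function(j) a * (j + 1) * (j + ga))
}

#' @export
heun_recurrence.confluent_heun <- function(params, include_accessory = TRUE) {
  al <- params$alpha; ga <- params$gamma; de <- params$delta; ep <- params$epsilon
  qq <- if (include_accessory) params$q else 0
  # Q_j grouping fixed by the ODE-residual arbiter: substituting the series
  # into the confluent equation gives the middle coefficient
  # j(j-1) + j(gamma+delta-epsilon) + q, consistent with the a -> Inf
  # confluence of the general family
  three_term_recurrence(
    P = function(j) (1 - j) * ep - al,
    Qt = function(j) j * (j - 1) + j * (ga + de - ep) + qq,
    R = function(j) (j + 1) * (j + ga))
}

#' Closed-form Heun series coefficients
#'
#' Computes \eqn{C_0..C_n} of the index-0 Frobenius solution from the
#' closed form
#' \eqn{C_i = [\,q\,\phi_{i-1}^{i-1}(q) - R_0 P_1 \phi_{i-2}^{i-1}(q)\,] /
#' \prod_{k<i} R_k}, the orthogonal polynomials being built on the bare
#' \eqn{Q_j} family and evaluated at the accessory parameter.  This is
#' identical to running [closed_form_C()] on the shifted family
#' \eqn{\tilde{Q}_j = Q_j + q} at \eqn{x = 0}.
#'
#' @param params a [general_heun()] or [confluent_heun()] object.
#' @param n truncation order (`n >= 0`).
#' @return Object of class `"heun_series"`: list with `params`,
#'   `coefficients` (length `n + 1`), `n`.
#' @export
heun_series <- function(params, n) {
  stopifnot(inherits(params, "heun_params"), n >= 0, n == round(n))
  rec <- heun_recurrence(params, include_accessory = FALSE)
  co <- vapply(0:n, function(i) closed_form_C(rec, i, x = params$q), numeric(1))
  structure(list(params = params, coefficients = co, n = n),
            class = "heun_series")
}

#' @export
print.heun_series <- function(x, ...) {
  cat("<Heun Frobenius series>  order n =", x$n, "\n")
  utils::head(x$coefficients, 8L) |> print()
  if (x$n > 7L) cat("  ...\n")
  invisible(x)
}

#' Write Heun series coefficients as TSV
#' @param series a [heun_series()] object.
#' @param file path to write to.
#' @export
write_series_tsv <- function(series, file) {
  utils::write.table(data.frame(j = 0:series$n,
                                Re_C = Re(series$coefficients),
                                Im_C = Im(series$coefficients)),
                     file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.heun_radius <- function(params) {
  if (inherits(params, "general_heun")) min(1, abs(params$a)) else 1
}

# coefficients up to n by forward recursion (cheap, stable for convergent z)
.heun_coefs_fwd <- function(params, n) {
  rec <- heun_recurrence(params, include_accessory = TRUE)
  forward_substitution(rec, n)
}

#' Evaluate a Heun function by guarded series summation
#'
#' Sums the index-0 Frobenius series at `z`, stopping when two consecutive
#' tail terms fall below `tol` (relative to the partial sum) or when
#' `n_max` terms have been used.  Points with \eqn{|z| \ge r}, where
#' \eqn{r = \min(1, |a|)} for the general equation and \eqn{r = 1} for the
#' confluent one, are refused unless the series is detected to truncate to
#' a polynomial (in which case the finite sum is valid everywhere).
#'
#' @param params a [general_heun()] or [confluent_heun()] object.
#' @param z evaluation point (may be complex).
#' @param tol relative tail tolerance.
#' @param n_max order cap.
#' @return Object of class `"heun_eval"`: list with `value`, `terms`
#'   (number of series terms used), `tail_bound` (magnitude of the last
#'   neglected term), `converged`.
#' @export
heun_eval <- function(params, z, tol = 1e-12, n_max = 400) {
  stopifnot(inherits(params, "heun_params"))
  r <- .heun_radius(params)
  if (z == 0)
    return(structure(list(value = if (is.complex(z)) 0i + 1 else 1,
                          terms = 1L, tail_bound = 0, converged = TRUE),
                     class = "heun_eval"))
  rec <- heun_recurrence(params, include_accessory = TRUE)
  # generate coefficients incrementally; a row with P_m = 0 decouples the
  # tail, so C_m ~ 0 there means the series is exactly a polynomial
  co <- numeric(0)
  Cm1 <- 0; C <- 1
  polynomial <- FALSE
  for (j in 0:n_max) {
    co[j + 1L] <- C
    if (j >= 1L && ttr_coef(rec, j, "P") == 0 &&
        abs(C) <= 1e-8 * max(abs(co[seq_len(j)]))) {
      co[j + 1L] <- 0
      polynomial <- TRUE
      break
    }
    row <- .ttr_row_dbl(rec, j)
    if (row[["R"]] == 0) stop("singular recurrence: R_", j, " = 0", call. = FALSE)
    Cn <- (row[["Qt"]] * C - row[["P"]] * Cm1) / row[["R"]]
    Cm1 <- C; C <- Cn
    if (!is.finite(C)) { co <- co[seq_len(j + 1L)]; break }
  }
  if (abs(z) >= r && !polynomial)
    stop("convergence-domain error: |z| = ", format(abs(z)),
         " >= radius ", format(r), " and the series is not polynomial",
         call. = FALSE)
  s <- if (is.complex(z)) 0i else 0
  used <- 0L; small <- 0L; conv <- FALSE; last <- 0
  for (j in seq_along(co)) {
    term <- co[j] * z^(j - 1L)
    s <- s + term
    used <- j; last <- abs(term)
    if (abs(term) < tol * (1 + abs(s))) small <- small + 1L else small <- 0L
    if (small >= 2L) { conv <- TRUE; break }
  }
  if (!conv && polynomial) conv <- TRUE
  if (!conv)
    warning("series did not meet the tail tolerance within n_max = ", n_max,
            " terms; returning the partial value")
  structure(list(value = s, terms = used, tail_bound = last,
                 converged = conv), class = "heun_eval")
}

#' @export
print.heun_eval <- function(x, ...) {
  cat("<Heun evaluation>  value =", format(x$value), " terms =", x$terms,
      " tail <", format(x$tail_bound), "\n")
  invisible(x)
}

# y, y', y'' of the truncated series at (possibly complex) z
.series_derivs <- function(co, z) {
  j <- seq_along(co) - 1
  y <- sum(co * z^j)
  yp <- sum(co[-1] * j[-1] * z^(j[-1] - 1))
  jpp <- j[j >= 2]
  ypp <- sum(co[jpp + 1] * jpp * (jpp - 1) * z^(jpp - 2))
  list(y = y, yp = yp, ypp = ypp)
}

#' Residual of a truncated Heun series in its differential equation
#'
#' Substitutes the truncated series and its first two derivatives into the
#' polynomial-coefficient form of the Heun equation (general:
#' \eqn{z(z-1)(z-a) y'' + [\gamma(z-1)(z-a) + \delta z(z-a) +
#' \epsilon z(z-1)] y' + (\alpha\beta z - q) y}; confluent:
#' \eqn{z(z-1) y'' + [\epsilon z(z-1) + \gamma(z-1) + \delta z] y' +
#' (\alpha z - q) y}) and returns the largest absolute value over the
#' supplied points.  For points inside the convergence disc the residual
#' decays geometrically with the truncation order; it is the arbiter used
#' to validate the recurrence coefficient grouping.
#'
#' @param series a [heun_series()] object (or any list with `params` and
#'   `coefficients`).
#' @param z_points points strictly inside the convergence disc.
#' @return Maximum absolute residual.
#' @export
heun_ode_residual <- function(series, z_points) {
  params <- series$params
  co <- series$coefficients
  r <- .heun_radius(params)
  if (any(abs(z_points) >= r))
    stop("z point outside the convergence disc (|z| >= ", format(r), ")",
         call. = FALSE)
  res <- vapply(z_points, function(z) {
    d <- .series_derivs(co, z)
    if (inherits(params, "general_heun")) {
      a <- params$a
      lhs <- z * (z - 1) * (z - a) * d$ypp +
        (params$gamma * (z - 1) * (z - a) + params$delta * z * (z - a) +
           params$epsilon * z * (z - 1)) * d$yp +
        (params$alpha * params$beta * z - params$q) * d$y
    } else {
      lhs <- z * (z - 1) * d$ypp +
        (params$epsilon * z * (z - 1) + params$gamma * (z - 1) +
           params$delta * z) * d$yp +
        (params$alpha * z + params$q) * d$y
    }
    abs(lhs)
  }, numeric(1))
  max(res)
}

#' Independent initial-value oracle for Heun evaluation
#'
#' Integrates the Heun differential equation as an initial-value problem
#' along the real axis with [deSolve::lsoda()], starting just off the
#' regular singular point at 0 (initial data from a short Taylor start with
#' \eqn{y(0) = 1}, \eqn{y'(0) = C_1}) and returns \eqn{y(z)}.  Used as the
#' cross-check for [heun_eval()]; it shares nothing with the closed-form
#' series path beyond the low-order Taylor seed.
#'
#' Starting the integration exactly at 0 is impossible (the point is
#' regular singular) and starting too close to it is ill-conditioned when
#' the second Frobenius index \eqn{1 - \gamma} exceeds 1: rounding in the
#' initial data excites the subdominant solution, amplified by
#' \eqn{(z/z_0)^{1-\gamma}}.  The oracle therefore starts at
#' \eqn{z_0 = 0.05\,r} with a order-14 Frobenius seed (truncation error
#' below \eqn{10^{-18}}), which keeps the excitation below \eqn{10^{-11}}
#' for the parameter ranges of the validation suite.
#'
#' @param params a [general_heun()] or [confluent_heun()] object (real
#'   parameters).
#' @param z real target point with `0 < z < r`.
#' @param z0 start point of the integration; default `0.05 * r`.
#' @return \eqn{y(z)} as a double.
#' @export
heun_ode_oracle <- function(params, z, z0 = NULL) {
  r <- .heun_radius(params)
  if (is.null(z0)) z0 <- 0.05 * r
  stopifnot(is.numeric(z), length(z) == 1L, z > z0, z < r)
  co <- .heun_coefs_fwd(params, 14L)
  j <- 0:14
  y0 <- sum(co * z0^j)
  yp0 <- sum(co[-1] * j[-1] * z0^(j[-1] - 1))
  rhs <- if (inherits(params, "general_heun")) {
    function(t, y, parms) {
      p <- params$gamma / t + params$delta / (t - 1) + params$epsilon / (t - params$a)
      f <- (params$alpha * params$beta * t - params$q) /
        (t * (t - 1) * (t - params$a))
      list(c(y[2], -p * y[2] - f * y[1]))
    }
  } else {
    function(t, y, parms) {
      p <- params$epsilon + params$gamma / t + params$delta / (t - 1)
      f <- (params$alpha * t + params$q) / (t * (t - 1))
      list(c(y[2], -p * y[2] - f * y[1]))
    }
  }
  sol <- deSolve::lsoda(c(y0, yp0), times = c(z0, z), func = rhs,
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[nrow(sol), 2L])
}
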