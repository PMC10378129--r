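# The fitting interface: spectral_decomposition() returns a classed object
# bundling spectrum, eigenbasis, stationary distribution and generator,
# with the usual modelling methods.

#' Full spectral decomposition of a choice model or birth-death chain
#'
#' The package's central fitting function.  Computes the complete
#' eigendecomposition of the model's master equation: decay rates
#' \eqn{0 = \lambda_0 < \lambda_1 \le \ldots \le \lambda_N} (by the
#' accessory-parameter quantization polynomial for choice models, or the
#' dense symmetrized eigensolver), relaxation times \eqn{1/\lambda_i}, the
#' stationary distribution, and the orthogonal eigenbasis used for time
#' propagation.
#'
#' @param model a [binary_choice_model()], [vacillating_voter_model()], or
#'   bare [birth_death_generator()].
#' @param method `"recurrence"` for the quantization-polynomial route
#'   (choice models only), `"dense"` for the symmetrized eigensolver.
#' @return Object of class `"ctmc_spectrum"` with fields `model`,
#'   `generator`, `decay_rates`, `relaxation_times`, `stationary`,
#'   `method`, and the internal propagation basis.  Supports `print`,
#'   `summary`, `coef` (decay rates), `predict` (time evolution),
#'   `simulate` (Gillespie trajectories), `residuals` (eigen-relation
#'   defects) and `plot`.
#' @examples
#' m <- binary_choice_model(N = 10, eps1 = 0.7, eps2 = 1.3, mu1 = 0.9, mu2 = 1.7)
#' fit <- spectral_decomposition(m)
#' fit
#' coef(fit)[2]           # slowest nonzero decay rate
#' head(summary(fit)$relaxation)
#' @export
spectral_decomposition <- function(model, method = c("recurrence", "dense")) {
  method <- match.arg(method)
  if (inherits(model, "birth_death_generator")) {
    g <- model
    if (method == "recurrence")
      stop("the recurrence route needs a choice model; use method = \"dense\"")
  } else {
    stopifnot(inherits(model, "choice_model"))
    g <- generator(model)
  }
  basis <- .sym_eigen(g)
  if (is.null(basis))
    stop("generator has a vanishing interior rate; spectral decomposition ",
         "requires an irreducible chain")
  lam <- if (method == "recurrence") as.numeric(eigen_spectrum(model))
         else { v <- basis$lam; v[which.min(abs(v))] <- 0; sort(v) }
  structure(list(model = if (inherits(model, "choice_model")) model else NULL,
                 generator = g,
                 decay_rates = lam,
                 relaxation_times = ifelse(lam > 0, 1 / lam, Inf),
                 stationary = stationary_distribution(g),
                 basis = basis,
                 method = method),
            class = "ctmc_spectrum")
}

#' @export
print.ctmc_spectrum <- function(x, ...) {
  cat("Spectral decomposition of a one-step CTMC (states 0..",
      x$generator$N, ")\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  lam <- x$decay_rates
  cat("  method:", x$method, "\n")
  cat("  decay rates: 0,", paste(signif(lam[lam > 0][1:min(3, sum(lam > 0))], 6),
                                 collapse = ", "),
      if (sum(lam > 0) > 3) ", ...", "\n")
  cat("  dominant relaxation time 1/lambda_1 =",
      signif(1 / lam[lam > 0][1], 6), "\n")
  invisible(x)
}

#' @export
summary.ctmc_spectrum <- function(object, ...) {
  out <- list(relaxation = relaxation_report(object),
              stationary = object$stationary,
              N = object$generator$N,
              method = object$method)
  class(out) <- "summary.ctmc_spectrum"
  out
}

#' @export
print.summary.ctmc_spectrum <- function(x, ...) {
  cat("Relaxation spectrum (", x$method, " route), states 0..", x$N, "\n",
      sep = "")
  print(utils::head(x$relaxation, 8L), row.names = FALSE)
  if (nrow(x$relaxation) > 8L) cat("  ...\n")
  cat("Stationary distribution summary:\n")
  print(summary(x$stationary))
  invisible(x)
}

#' @export
coef.ctmc_spectrum <- function(object, ...) object$decay_rates

#' @param object a `ctmc_spectrum` fit.
#' @param P0 initial probability vector; defaults to a point mass at
#'   state 0.
#' @param times nonnegative times.
#' @param ... unused.
#' @rdname spectral_decomposition
#' @export
predict.ctmc_spectrum <- function(object, P0 = NULL, times = 1, ...) {
  N <- object$generator$N
  if (is.null(P0)) P0 <- c(1, numeric(N))
  evolve(object$generator, P0, times)
}

#' @param nsim number of SSA trajectories.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n0 initial state for simulation.
#' @param t_end end time for simulation.
#' @rdname spectral_decomposition
#' @export
simulate.ctmc_spectrum <- function(object, nsim = 1, seed = 1,
                                   n0 = 0, t_end = 1, ...) {
  gillespie_simulate(object$generator, n0 = n0, t_end = t_end,
                     n_traj = nsim, seed = seed)
}

#' @export
residuals.ctmc_spectrum <- function(object, ...) {
  A <- as.matrix(object$generator)
  U <- object$basis$U; sp <- object$basis$sqrtpi
  lam <- object$basis$lam
  vapply(seq_along(lam), function(i) {
    v <- sp * U[, i]
    max(abs(A %*% v + lam[i] * v))
  }, numeric(1))
}

#' @export
plot.ctmc_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$stationary, names.arg = 0:x$generator$N,
                    xlab = "n", ylab = expression(pi(n)),
                    main = "stationary distribution", border = NA)
  lam <- x$decay_rates
  graphics::plot(seq_along(lam) - 1L, lam, pch = 16, xlab = "mode i",
                 ylab = expression(lambda[i]), main = "decay-rate spectrum")
  invisible(x)
}
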