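# Binary-choice CTMC models: the fully asymmetric recruitment model and
# the vacillating voter model, their tridiagonal generators, stationary
# distributions, and stochastic simulation oracles.

#' Fully asymmetric binary-choice (recruitment) model
#'
#' A population of `N` agents chooses between a left and a right option.
#' Each agent switches spontaneously (left-to-right at rate `eps1` per
#' agent, right-to-left at `eps2`) and is recruited by agents of the other
#' opinion through pairwise contact (rates `mu1`, `mu2` per pair).  The
#' state `n = 0..N` counts right-deciders; transition propensities are
#' \eqn{b(n) = (N-n)\epsilon_1 + \mu_1 n(N-n)} (up) and
#' \eqn{d(n) = n\epsilon_2 + \mu_2 n(N-n)} (down).
#'
#' @param N number of agents (`N >= 2`).
#' @param eps1,eps2 spontaneous switching rates (per agent per time).
#' @param mu1,mu2 recruitment rates (per agent pair per time); both must be
#'   positive for the Heun parameter map.
#' @return Object of class `c("binary_choice_model", "choice_model")`.
#' @export
binary_choice_model <- function(N, eps1, eps2, mu1, mu2) {
  stopifnot(N >= 2, N == round(N), eps1 > 0, eps2 > 0, mu1 > 0, mu2 > 0)
  structure(list(N = as.integer(N), eps1 = eps1, eps2 = eps2,
                 mu1 = mu1, mu2 = mu2),
            class = c("binary_choice_model", "choice_model"))
}

#' Vacillating voter model
#'
#' `N` agents hold one of two opinions.  An agent reconsiders at unit rate:
#' with probability `pd` it flips spontaneously; otherwise it consults
#' other agents, and a flip requires disagreement confirmed by a second
#' consultation (see the package vignette for the exact consultation
#' scheme the propensities encode).  The resulting one-step propensities
#' are, with `n` the number of right-deciders,
#' \deqn{b(n) = p_d (N-n) + (1-p_d)(N-n)\frac{n}{N-1}\left(1 +
#'   \frac{N-n}{N-1}\right), \qquad d(n) = b(N-n).}
#' The model is symmetric under \eqn{n \leftrightarrow N-n} and shows
#' stationary trimodality for small-to-intermediate `pd`.
#'
#' @param N number of agents (`N >= 3`).
#' @param pd spontaneous flip probability, `0 < pd < 1`.
#' @return Object of class `c("vacillating_voter_model", "choice_model")`.
#' @export
vacillating_voter_model <- function(N, pd) {
  stopifnot(N >= 3, N == round(N), pd > 0, pd < 1)
  structure(list(N = as.integer(N), pd = pd),
            class = c("vacillating_voter_model", "choice_model"))
}

#' @export
print.choice_model <- function(x, ...) {
  if (inherits(x, "binary_choice_model")) {
    cat("<binary choice model>  N =", x$N,
        sprintf(" eps = (%g, %g)  mu = (%g, %g)\n", x$eps1, x$eps2, x$mu1, x$mu2))
  } else {
    cat("<vacillating voter model>  N =", x$N, " pd =", x$pd, "\n")
  }
  invisible(x)
}

#' Birth-death generator of a one-step chain
#'
#' Container for the tridiagonal generator of a continuous-time Markov
#' chain on states `0..N`: `birth[n+1]` is the rate \eqn{n \to n+1},
#' `death[n+1]` the rate \eqn{n \to n-1}.  Requires `birth[N+1] = 0`,
#' `death[1] = 0` and nonnegative rates; the implied matrix (see
#' [as.matrix.birth_death_generator()]) has exactly zero column sums.
#'
#' @param birth,death numeric vectors of length `N + 1`.
#' @return Object of class `"birth_death_generator"`.
#' @export
birth_death_generator <- function(birth, death) {
  stopifnot(length(birth) == length(death), length(birth) >= 2)
  N <- length(birth) - 1L
  if (birth[N + 1L] != 0) stop("birth rate out of the top state must be 0")
  if (death[1L] != 0) stop("death rate out of state 0 must be 0")
  if (any(birth < 0) || any(death < 0)) stop("rates must be nonnegative")
  structure(list(N = N, birth = as.numeric(birth), death = as.numeric(death)),
            class = "birth_death_generator")
}

#' @export
print.birth_death_generator <- function(x, ...) {
  cat("<birth-death generator>  states 0..", x$N, "\n", sep = "")
  print(utils::head(data.frame(n = 0:x$N, birth = x$birth, death = x$death), 8L))
  if (x$N > 7L) cat("  ...\n")
  invisible(x)
}

#' Dense generator matrix
#'
#' Assembles the `(N+1) x (N+1)` generator `A` with the column convention
#' \eqn{\partial_t P = A P}: `A[n+1, n]` holds the birth rate out of state
#' `n - 1`, and each diagonal entry is exactly the negated sum of its
#' column's off-diagonal rates, so column sums vanish (to within one
#' floating rounding of the exit rate when re-summed).
#'
#' @param x a [birth_death_generator()].
#' @param ... unused.
#' @export
as.matrix.birth_death_generator <- function(x, ...) {
  N <- x$N
  A <- matrix(0, N + 1L, N + 1L)
  for (n in 0:N) {
    A[n + 1L, n + 1L] <- -(x$birth[n + 1L] + x$death[n + 1L])
    if (n < N) A[n + 2L, n + 1L] <- x$birth[n + 1L]
    if (n > 0) A[n, n + 1L] <- x$death[n + 1L]
  }
  A
}

#' Generator of a choice model
#'
#' @param model a [binary_choice_model()] or [vacillating_voter_model()].
#' @return A [birth_death_generator()].
#' @export
generator <- function(model) UseMethod("generator")

#' @export
generator.binary_choice_model <- function(model) binary_choice_generator(model)

#' @export
generator.vacillating_voter_model <- function(model) vacillating_generator(model)

#' @rdname generator
#' @param m a [binary_choice_model()].
#' @export
binary_choice_generator <- function(m) {
  stopifnot(inherits(m, "binary_choice_model"))
  n <- 0:m$N
  birth_death_generator(
    birth = (m$N - n) * m$eps1 + m$mu1 * n * (m$N - n),
    death = n * m$eps2 + m$mu2 * n * (m$N - n))
}

#' @rdname generator
#' @export
vacillating_generator <- function(m) {
  stopifnot(inherits(m, "vacillating_voter_model"))
  N <- m$N; pd <- m$pd
  b <- function(n) pd * (N - n) +
    (1 - pd) * (N - n) * (n / (N - 1)) * (1 + (N - n) / (N - 1))
  n <- 0:N
  birth_death_generator(birth = b(n), death = b(N - n))
}

#' Heun parameter map of the binary-choice model
#'
#' The generating function \eqn{G(z, t) = \sum_n P(n, t) z^n} of the
#' binary-choice master equation separates as \eqn{G \sim f_\lambda(z)
#' e^{-\lambda t}} with \eqn{f_\lambda} a general Heun function
#' \eqn{H(a, q(\lambda); \alpha, \beta, \gamma, 0; z)}.  Substituting the
#' generating-function ansatz into the master equation gives
#' \deqn{a = \mu_2/\mu_1,\quad \alpha = -N,\quad \beta = \epsilon_1/\mu_1,
#'   \quad \gamma = -(N-1) - \epsilon_2/\mu_2,\quad \delta = 0,}
#' \eqn{\epsilon} from the Fuchs relation, and the accessory parameter
#' \eqn{q(\lambda) = (\lambda - N\epsilon_1)/\mu_1} (decay-rate convention
#' \eqn{e^{-\lambda t}}).  Because \eqn{\alpha = -N}, physical
#' eigenfunctions are degree-`N` polynomials and the quantized
#' \eqn{q^\ast} map back to decay rates through
#' \eqn{\lambda = N\epsilon_1 + \mu_1 q^\ast}.
#'
#' @param m a [binary_choice_model()].
#' @return Object of class `"heun_lambda_map"`: the fixed exponent
#'   parameters plus `q_of_lambda`, `lambda_of_q`, and `params_at(lambda)`
#'   returning a [general_heun()] object.
#' @export
binary_choice_heun_map <- function(m) {
  stopifnot(inherits(m, "binary_choice_model"))
  N <- m$N
  a <- m$mu2 / m$mu1
  alpha <- -N
  beta <- m$eps1 / m$mu1
  gamma <- -(N - 1) - m$eps2 / m$mu2
  delta <- 0
  epsilon <- alpha + beta + 1 - gamma - delta
  q_of_lambda <- function(lambda) (lambda - N * m$eps1) / m$mu1
  lambda_of_q <- function(q) N * m$eps1 + m$mu1 * q
  params_at <- function(lambda)
    general_heun(a = a, q = q_of_lambda(lambda), alpha = alpha, beta = beta,
                 gamma = gamma, delta = delta, epsilon = epsilon)
  structure(list(a = a, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, epsilon = epsilon,
                 q_of_lambda = q_of_lambda, lambda_of_q = lambda_of_q,
                 params_at = params_at, model = m),
            class = "heun_lambda_map")
}

#' @export
print.heun_lambda_map <- function(x, ...) {
  cat("<Heun parameter map>  a =", format(x$a),
      " alpha =", format(x$alpha), " beta =", format(x$beta),
      "\n  gamma =", format(x$gamma), " delta = 0, epsilon =",
      format(x$epsilon), "\n  q(lambda) = (lambda - N eps1)/mu1\n")
  invisible(x)
}

#' Spectral recurrence of a choice model
#'
#' Packages the accessory-free three-term recurrence whose quantization
#' polynomial (see [quantization_polynomial()]) encodes the model's
#' eigenvalues, together with the maps between the accessory parameter and
#' the decay rate.  For the binary-choice model the rows are the general
#' Heun families of [binary_choice_heun_map()].  For the vacillating voter
#' model the rows are the master-equation rows in the scaled basis that
#' carries \eqn{q(\lambda) = (N-1)(p_d N - \lambda)}:
#' \eqn{R_j = (N-1)^2 d(j+1)}, \eqn{Q_j = (N-1)(b_j + d_j) - N(N-1)p_d},
#' \eqn{P_j = b(j-1)}, with the j = 0 boundary row pinned to
#' \eqn{(N-1)((N-1)p_d + N(1-p_d))\, C_1 = q(\lambda)\, C_0} (installed as
#' an explicit row override; in this basis it coincides with the generic
#' row).
#'
#' @param model a [binary_choice_model()] or [vacillating_voter_model()].
#' @return Object of class `"spectral_recurrence"`: list with `rec` (the
#'   accessory-free [three_term_recurrence()]), `N`, `q_of_lambda`,
#'   `lambda_of_q`.
#' @export
spectral_recurrence <- function(model) UseMethod("spectral_recurrence")

#' @export
spectral_recurrence.binary_choice_model <- function(model) {
  map <- binary_choice_heun_map(model)
  # build the Heun coefficient family directly: the strict gamma check of
  # general_heun() does not apply to the polynomial (quantized) sector,
  # which only touches R_0..R_{N-1}, all nonzero since gamma < -(N-1)
  a <- map$a; al <- map$alpha; be <- map$beta; ga <- map$gamma
  de <- map$delta; ep <- map$epsilon
  rec <- three_term_recurrence(
    P = function(j) (j - 1 + al) * (j - 1 + be),
    Qt = function(j) j * ((j - 1 + ga) * (1 + a) + a * de + ep),
    R = function(j) a * (j + 1) * (j + ga))
  structure(list(rec = rec, N = model$N, q_of_lambda = map$q_of_lambda,
                 lambda_of_q = map$lambda_of_q, model = model),
            class = "spectral_recurrence")
}

#' @rdname spectral_recurrence
#' @param m a [vacillating_voter_model()].
#' @export
vacillating_recurrence <- function(m) spectral_recurrence(m)

#' @export
spectral_recurrence.vacillating_voter_model <- function(model) {
  N <- model$N; pd <- model$pd
  g <- vacillating_generator(model)
  bd <- function(n) if (n < 0 || n > N) 0 else g$birth[n + 1L]
  dd <- function(n) if (n < 0 || n > N) 0 else g$death[n + 1L]
  rec <- three_term_recurrence(
    P = function(j) bd(j - 1),
    Qt = function(j) (N - 1) * (bd(j) + dd(j)) - N * (N - 1) * pd,
    R = function(j) (N - 1)^2 * dd(j + 1),
    overrides = list("0" = list(
      Qt = 0,
      R = (N - 1) * ((N - 1) * pd + N * (1 - pd)))))
  structure(list(rec = rec, N = N,
                 q_of_lambda = function(lambda) (N - 1) * (pd * N - lambda),
                 lambda_of_q = function(q) pd * N - q / (N - 1),
                 model = model),
            class = "spectral_recurrence")
}

#' @export
print.spectral_recurrence <- function(x, ...) {
  cat("<spectral recurrence>  N =", x$N, " model:", class(x$model)[1L], "\n")
  invisible(x)
}

#' Stationary distribution of a birth-death chain
#'
#' Detailed balance gives \eqn{\pi(n) \propto \prod_{k<n} b(k)/d(k+1)};
#' computed in log space and normalized.  Requires irreducibility
#' (`b(n) > 0` below the top state, `d(n) > 0` above 0).
#'
#' @param g a [birth_death_generator()].
#' @return Probability vector over states `0..N`.
#' @export
stationary_distribution <- function(g) {
  stopifnot(inherits(g, "birth_death_generator"))
  N <- g$N
  if (any(g$birth[1:N] <= 0))
    stop("reducible chain: birth rate vanishes at state n = ",
         which(g$birth[1:N] <= 0)[1L] - 1L, call. = FALSE)
  if (any(g$death[2:(N + 1L)] <= 0))
    stop("reducible chain: death rate vanishes at state n = ",
         which(g$death[2:(N + 1L)] <= 0)[1L], call. = FALSE)
  logpi <- c(0, cumsum(log(g$birth[1:N]) - log(g$death[2:(N + 1L)])))
  pi <- exp(logpi - max(logpi))
  pi / sum(pi)
}

#' Exact stochastic simulation (SSA) of a birth-death chain
#'
#' Simulates `n_traj` independent trajectories of the chain by the direct
#' (Gillespie) method, vectorized synchronously across trajectories, and
#' returns the states at `t_end`.
#'
#' @param g a [birth_death_generator()].
#' @param n0 initial state (single value, recycled).
#' @param t_end end time (`>= 0`).
#' @param n_traj number of trajectories.
#' @param seed mandatory RNG seed for reproducibility.
#' @return Integer vector of length `n_traj` with the states at `t_end`.
#' @export
gillespie_simulate <- function(g, n0, t_end, n_traj, seed) {
  stopifnot(inherits(g, "birth_death_generator"))
  if (t_end < 0) stop("t_end must be nonnegative")
  stopifnot(n0 >= 0, n0 <= g$N, length(seed) == 1L)
  set.seed(as.integer(seed))
  state <- rep.int(as.integer(n0), n_traj)
  t <- numeric(n_traj)
  active <- rep.int(TRUE, n_traj)
  b <- g$birth; d <- g$death
  while (any(active)) {
    s <- state[active] + 1L
    rate <- b[s] + d[s]
    frozen <- rate == 0
    if (any(frozen)) {
      idx <- which(active)[frozen]
      active[idx] <- FALSE
      if (!any(active)) break
      s <- state[active] + 1L
      rate <- b[s] + d[s]
    }
    dt <- stats::rexp(length(s), rate)
    tnew <- t[active] + dt
    done <- tnew >= t_end
    up <- stats::runif(length(s)) < b[s] / rate
    idx <- which(active)
    t[idx] <- tnew
    move <- !done
    state[idx[move]] <- state[idx[move]] + ifelse(up[move], 1L, -1L)
    active[idx[done]] <- FALSE
  }
  state
}

#' Rule-based simulation of the vacillating voter model
#'
#' Agent-level simulation by explicit consultations rather than through
#' the aggregated propensities: at each step one agent is chosen uniformly
#' and reconsiders.  With probability `pd` the spontaneous channel fires
#' (flip with probability 1/2); otherwise the agent consults another agent
#' chosen uniformly among the remaining `N - 1`.  Agreement ends the step.
#' On disagreement a second consultation is drawn uniformly among the
#' `N - 1` agents other than the first consultant: the agent flips surely
#' if the second consultant agrees with it, and with probability 1/2 if it
#' also disagrees.  The halved flip probabilities uniformize the
#' propensities so each embedded step is exactly one transition attempt of
#' the chain of [vacillating_generator()] slowed by a factor 2; stationary
#' quantities are unaffected by the time rescaling.
#'
#' @param m a [vacillating_voter_model()].
#' @param n_steps number of reconsideration events to simulate.
#' @param n0 initial number of right-deciders.
#' @param seed mandatory RNG seed.
#' @param burnin steps to discard before recording.
#' @return Integer vector of recorded states (one per step after burn-in).
#' @export
vacillating_rule_simulate <- function(m, n_steps, n0 = round(m$N / 2), seed,
                                      burnin = 0L) {
  stopifnot(inherits(m, "vacillating_voter_model"), length(seed) == 1L)
  set.seed(as.integer(seed))
  N <- m$N; pd <- m$pd
  n <- as.integer(n0)
  out <- integer(n_steps)
  u_agent <- stats::runif(n_steps + burnin)
  u_chan <- stats::runif(n_steps + burnin)
  u_c1 <- stats::runif(n_steps + burnin)
  u_c2 <- stats::runif(n_steps + burnin)
  u_flip <- stats::runif(n_steps + burnin)
  for (s in seq_len(n_steps + burnin)) {
    is_right <- u_agent[s] < n / N
    n_dis <- if (is_right) N - n else n       # others disagreeing
    flip <- FALSE
    if (u_chan[s] < pd) {
      flip <- u_flip[s] < 0.5                 # spontaneous channel, halved
    } else if (u_c1[s] < n_dis / (N - 1)) {   # first consultant disagrees
      # second consultant: uniform among the N-1 agents other than the
      # first consultant; N - n_dis of them (incl. the focal agent) agree
      agree2 <- u_c2[s] < (N - n_dis) / (N - 1)
      flip <- agree2 || u_flip[s] < 0.5
    }
    if (flip) n <- n + (if (is_right) -1L else 1L)
    if (s > burnin) out[s - burnin] <- n
  }
  out
}
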