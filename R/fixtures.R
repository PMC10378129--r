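# Seeded random fixtures: recurrence families, birth-death chains, Heun
# parameter draws.  All randomness goes through the base RNG seeded once
# per call; the same seed reproduces the same fixture byte for byte.

#' Random exact-rational three-term recurrence family
#'
#' Draws rational coefficient tables \eqn{P_j, \tilde{Q}_j, R_j} with
#' numerators in `-mag..mag` and denominators in `1..den_max`, the
#' \eqn{R_j} bounded away from zero (|numerator| >= 1 and |value| >= 0.1).
#'
#' @param seed RNG seed (mandatory).
#' @param i_max the family covers rows `0..i_max + 1`.
#' @param mag magnitude bound for numerators.
#' @param den_max bound for denominators.
#' @param mode arithmetic mode of the returned recurrence.
#' @return A [three_term_recurrence()] with rational tables; the drawn
#'   numerators/denominators are attached as attribute `"tables"`.
#' @export
fixture_recurrence <- function(seed, i_max = 40, mag = 12, den_max = 10,
                               mode = c("exact", "double")) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  nrow_ <- i_max + 2L
  draw_num <- function() sample(c(-(1:mag), 1:mag), nrow_, replace = TRUE)
  draw_den <- function() sample(1:den_max, nrow_, replace = TRUE)
  pn <- sample(-mag:mag, nrow_, replace = TRUE); pd <- draw_den()
  qn <- sample(-mag:mag, nrow_, replace = TRUE); qd <- draw_den()
  rn <- draw_num(); rd <- draw_den()
  # enforce |R_j| >= 0.1
  bad <- abs(rn / rd) < 0.1
  rn[bad] <- sign(rn[bad]) * pmax(abs(rn[bad]), ceiling(rd[bad] / 10))
  tabs <- list(P = list(num = pn, den = pd), Qt = list(num = qn, den = qd),
               R = list(num = rn, den = rd))
  rec <- three_term_recurrence(P = tabs$P, Qt = tabs$Qt, R = tabs$R, mode = mode)
  attr(rec, "tables") <- tabs
  rec
}

#' Random irreducible birth-death chain
#'
#' @param seed RNG seed.
#' @param N top state.
#' @param rate_range range of the uniformly drawn positive rates.
#' @return A [birth_death_generator()].
#' @export
fixture_birth_death <- function(seed, N = 10, rate_range = c(0.1, 2)) {
  set.seed(as.integer(seed))
  b <- c(stats::runif(N, rate_range[1], rate_range[2]), 0)
  d <- c(0, stats::runif(N, rate_range[1], rate_range[2]))
  birth_death_generator(b, d)
}

#' Random valid Heun parameter draw
#'
#' Draws real parameters with `gamma` at distance at least 0.1 from the
#' non-positive integers and, for the general equation, `|a|` in
#' `[1.2, 3]` so the unit evaluation points of the validation suite lie
#' inside the convergence disc.
#'
#' @param seed RNG seed.
#' @param type `"general"` or `"confluent"`.
#' @return A [general_heun()] or [confluent_heun()] object.
#' @export
fixture_heun <- function(seed, type = c("general", "confluent")) {
  type <- match.arg(type)
  set.seed(as.integer(seed))
  draw_gamma <- function() {
    repeat {
      g <- stats::runif(1, -3, 3)
      if (g > 0.1 || abs(g - round(g)) >= 0.1) return(g)
    }
  }
  if (type == "general") {
    a <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 3)
    general_heun(a = a, q = stats::runif(1, -2, 2),
                 alpha = stats::runif(1, -2, 2), beta = stats::runif(1, -2, 2),
                 gamma = draw_gamma(), delta = stats::runif(1, -2, 2))
  } else {
    confluent_heun(q = stats::runif(1, -2, 2), alpha = stats::runif(1, -2, 2),
                   gamma = draw_gamma(), delta = stats::runif(1, -2, 2),
                   epsilon = stats::runif(1, -2, 2))
  }
}

#' Generate a serialized fixture
#'
#' Dispatcher over the fixture kinds; the result is serialized through the
#' package JSON dialects, so the same seed yields byte-identical output.
#'
#' @param kind one of `"random_recurrence"`, `"random_birth_death"`,
#'   `"heun_params"`.
#' @param seed RNG seed (mandatory).
#' @param ... forwarded to the underlying fixture function.
#' @return A JSON string (class `"json"`).
#' @export
generate_fixture <- function(kind = c("random_recurrence", "random_birth_death",
                                      "heun_params"), seed, ...) {
  kind <- match.arg(kind)
  stopifnot(!missing(seed))
  obj <- switch(kind,
    random_recurrence = {
      rec <- fixture_recurrence(seed, ...)
      t <- attr(rec, "tables")
      list(kind = "recurrence",
           P = list(num = t$P$num, den = t$P$den),
           Qt = list(num = t$Qt$num, den = t$Qt$den),
           R = list(num = t$R$num, den = t$R$den))
    },
    random_birth_death = {
      g <- fixture_birth_death(seed, ...)
      list(kind = "birth_death", birth = g$birth, death = g$death)
    },
    heun_params = {
      p <- fixture_heun(seed, ...)
      c(list(kind = if (inherits(p, "general_heun")) "general_heun"
             else "confluent_heun"), unclass(p))
    })
  jsonlite::toJSON(c(obj, list(seed = as.integer(seed))),
                   auto_unbox = TRUE, digits = NA)
}
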