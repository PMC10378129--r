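# shared helpers: total-variation distance, local-maxima count, and a
# plain-R reference forward substitution independent of the package's
# closed-form path

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

count_modes <- function(p) {
  sum(vapply(seq_along(p), function(i) {
    l <- if (i > 1) p[i - 1] else -Inf
    r <- if (i < length(p)) p[i + 1] else -Inf
    p[i] > l && p[i] > r
  }, logical(1)))
}

# brute-force oracle written against the raw coefficient tables, not the
# package recurrence object
raw_forward <- function(P, Qt, R, i_max) {
  C <- numeric(i_max + 1)
  C[1] <- 1
  for (j in 0:(i_max - 1)) {
    prev <- if (j >= 1) C[j] else 0
    C[j + 2] <- (Qt(j) * C[j + 1] - P(j) * prev) / R(j)
  }
  C
}

const_rec <- function(mode = "double")
  three_term_recurrence(function(j) 1, function(j) 2, function(j) 1,
                        mode = mode)
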