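# Shared generators for property-style tests.

# Random symmetric matrix of order n with entries in roughly [-1, 1].
random_symmetric <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  (A + t(A)) / 2
}

# Random symmetric matrix guaranteed non-PD: spectrum forced to contain at
# least one negative and one positive eigenvalue.
random_nonpd <- function(n, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  d <- sort(stats::runif(n, -1, 5), decreasing = TRUE)
  d[n] <- -abs(d[n]) - 0.1
  d[1] <- abs(d[1]) + 0.1
  M <- Q %*% (d * t(Q))
  (M + t(M)) / 2
}

# Independent PD oracle: all leading principal minors strictly positive
# (Sylvester's criterion). Deliberately not eigenvalue-based.
pd_by_minors <- function(M) {
  all(vapply(seq_len(nrow(M)),
             function(k) det(M[seq_len(k), seq_len(k), drop = FALSE]) > 0,
             logical(1)))
}
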