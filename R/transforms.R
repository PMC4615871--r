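# Log-space numerics shared by the distribution code.
#
# The clone-size laws involve ratios of Gamma functions and Poisson kernels at
# sizes up to ~1e7; everything is therefore assembled in log space from
# all-positive terms (no cancellation anywhere in these transforms).

logaddexp <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(-abs(x - y)))
  # -Inf + -Inf must stay -Inf, not NaN
  both <- is.infinite(m) & m < 0
  out[both] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(1 - exp(x)) for x < 0, numerically stable on both ends
log1mexp <- function(x) {
  stopifnot(all(x <= 0))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# Triangular table of log Stirling numbers of the second kind, log S(q, n),
# n = 1..q, grown on demand and cached for the session.  Built by the standard
# recursion S(q, n) = n*S(q-1, n) + S(q-1, n-1), which is a sum of positive
# terms and hence stable in log space.
stirling2_log_row <- function(q) {
  stopifnot(q >= 1)
  rows <- .hemaclone_cache$stirling_rows
  if (is.null(rows)) rows <- list(0)  # S(1,1) = 1
  nhave <- length(rows)
  if (q > nhave) {
    for (qq in (nhave + 1):q) {
      prev <- rows[[qq - 1]]                    # n = 1..qq-1
      t1 <- c(log(seq_len(qq - 1)) + prev, -Inf) # n*S(qq-1, n), n = 1..qq
      t2 <- c(-Inf, prev)                        # S(qq-1, n-1)
      if (qq == 2) t2[1] <- -Inf                 # S(1,0) = 0
      rows[[qq]] <- logaddexp(t1, t2)
    }
    .hemaclone_cache$stirling_rows <- rows
  }
  rows[[q]]
}
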