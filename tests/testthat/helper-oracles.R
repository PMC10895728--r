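# Independent oracles, deliberately brute-force; none shares code with the
# implementation paths they check.

# Standard normal CDF by numerical integration of the density. The limit is
# capped at |z| = 40 (the tail beyond holds no double-precision mass) so the
# quadrature never has to find a narrow bump inside an enormous interval.
normCdfNumeric <- function(z) {
  vapply(z, function(zi) {
    lim <- sign(zi) * min(abs(zi), 40)
    0.5 + integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), 0, lim,
                    rel.tol = 1e-13, abs.tol = 1e-14)$value
  }, numeric(1))
}

# Brute-force DII: explicit per-parameter loop with the numerical CDF.
diiBruteForce <- function(intake, refTab) {
  total <- 0
  for (i in seq_len(nrow(refTab))) {
    p <- refTab$parameter[i]
    if (!p %in% names(intake)) next
    z <- (intake[[p]] - refTab$global_mean[i]) / refTab$global_sd[i]
    total <- total + (2 * normCdfNumeric(z) - 1) * refTab$effect_score[i]
  }
  total
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (doubling rule, capped at 1). Values must be tie-free.
mwEnumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii)
    sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Hypergeometric upper tail P[X >= k] by enumeration over all C(N, n) draws.
hyperEnumerate <- function(N, K, n, k) {
  draws <- combn(N, n)
  inTerm <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% inTerm))
  mean(hits >= k)
}

# AUC by looping over every positive/negative pair, ties counted 1/2.
aucBruteForce <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
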