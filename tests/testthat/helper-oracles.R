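# Independent oracles kept deliberately separate from the package's
# implementation paths.

# Scalar Weir-Cockerham (1984) two-population multilocus FST, written
# directly from the published variance components with explicit loops.
wc_oracle <- function(dos_a, dos_b) {
  num <- den <- 0
  for (l in seq_len(ncol(dos_a))) {
    ga <- dos_a[!is.na(dos_a[, l]), l]
    gb <- dos_b[!is.na(dos_b[, l]), l]
    n1 <- length(ga); n2 <- length(gb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    h1 <- mean(ga == 1); h2 <- mean(gb == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                               hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force two-sided rank-sum p-value: full enumeration of group
# assignments, counting those whose U deviates from its mean by at least
# the observed amount.
enumerate_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-12)
}
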