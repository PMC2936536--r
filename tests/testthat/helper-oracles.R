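# Independent brute-force oracles used by unit and acceptance tests.
# These transcribe the published formulas (or enumerate outcomes) in a
# deliberately different style from the package implementation.

# Weir & Cockerham (1984) variance components, r populations kept symbolic
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# Tajima (1989) D from a complete samples x sites dosage matrix; pi by
# counting pairwise differences per site
tajima_oracle <- function(g) {
  n <- 2L * nrow(g)
  cnt <- colSums(g)
  seg <- cnt > 0L & cnt < n
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  pi <- 0
  for (j in which(seg)) pi <- pi + cnt[j] * (n - cnt[j]) / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exhaustive hypergeometric upper tail
hyper_oracle <- function(k, K, n, N) {
  tot <- 0
  for (j in k:n)
    if (j <= K && (n - j) <= (N - K))
      tot <- tot + choose(K, j) * choose(N - K, n - j)
  tot / choose(N, n)
}

# EHH by enumerating all carrier pairs over the extension columns; each
# pair is compared at the sites where both alleles are called
ehh_oracle <- function(hmat, carriers, ext_cols) {
  if (length(carriers) < 2) return(NA_real_)
  same <- 0; tot <- 0
  for (i in seq_along(carriers)[-length(carriers)]) {
    for (j in (i + 1):length(carriers)) {
      x <- hmat[carriers[i], ext_cols]
      y <- hmat[carriers[j], ext_cols]
      both <- !is.na(x) & !is.na(y)
      tot <- tot + 1
      if (!any(x[both] != y[both])) same <- same + 1
    }
  }
  same / tot
}

# one-sided K-S statistic D+ = sup_x [F_bg(x) - F_path(x)], brute force
ks_d_oracle <- function(path_vals, bg_vals) {
  d <- 0
  for (t in c(path_vals, bg_vals))
    d <- max(d, mean(bg_vals <= t) - mean(path_vals <= t))
  d
}
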