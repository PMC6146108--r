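## Independent brute-force oracles, kept deliberately naive (explicit loops,
## textbook formulas) so they share no code path with the package.

bf_weighted_mean <- function(d, w) {
  num <- 0; den <- 0
  for (i in seq_along(d)) { num <- num + d[i] * w[i]; den <- den + w[i] }
  num / den
}

bf_weighted_var <- function(d, w) {
  m <- bf_weighted_mean(d, w)
  num <- 0; den <- 0
  for (i in seq_along(d)) { num <- num + w[i] * (d[i] - m)^2; den <- den + w[i] }
  num / den
}

bf_kish_n <- function(w) {
  s1 <- 0; s2 <- 0
  for (wi in w) { s1 <- s1 + wi; s2 <- s2 + wi^2 }
  s1^2 / s2
}

## step-up BH by direct minimization over ranks
bf_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- 1
    for (j in seq_len(m)) {
      if (r[j] >= r[i]) cand <- min(cand, p[j] * m / r[j])
    }
    q[i] <- min(cand, 1)
  }
  q
}

bf_welch <- function(mL, vL, nL, mC, vC, nC) {
  se2 <- vL / nL + vC / nC
  t <- (mL - mC) / sqrt(se2)
  df <- se2^2 / ((vL / nL)^2 / (nL - 1) + (vC / nC)^2 / (nC - 1))
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

bf_trapz <- function(z, r) {
  s <- 0
  for (i in seq_len(length(z) - 1))
    s <- s + (z[i + 1] - z[i]) * (r[i] + r[i + 1]) / 2
  s
}
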