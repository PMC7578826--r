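# Independent brute-force oracles used to validate the statistical
# primitives. These deliberately share no code with the implementation.

# AUC by direct enumeration of every case-control pair.
auc_enum <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration
# (probability-ordering rule), from first principles with choose().
fisher_enum <- function(t) {
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  px <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), 0)
  p_obs <- px[a - lo + 1]
  sum(px[px <= p_obs * (1 + 1e-7)])
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
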