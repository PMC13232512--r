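# Independent oracles used to cross-check the package's implementations.
# These are deliberately written in a different style (scalar loops, direct
# textbook formulas) and never call the code paths they check.

# Weir & Cockerham (1984) two-population theta-hat, one locus at a time,
# straight from the variance-component definitions.
wc_fst_oracle <- function(n1, ac1, het1, n2, ac2, het2) {
  if (n1 < 2 || n2 < 2) return(NA_real_)
  r <- 2
  p <- c(ac1 / (2 * n1), ac2 / (2 * n2))
  h <- c(het1 / n1, het2 / n2)
  n <- c(n1, n2)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# binomial upper tail P(X >= k) by term-by-term summation
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  tot <- 0
  for (i in k:n) tot <- tot + choose(n, i) * p^i * (1 - p)^(n - i)
  tot
}

# two-sided Fisher exact P by hypergeometric enumeration over all tables
# with the observed margins
fisher_p_oracle <- function(tab) {
  m <- rowSums(tab); k <- colSums(tab)
  lo <- max(0, k[1] - m[2]); hi <- min(k[1], m[1])
  probs <- sapply(lo:hi, function(x) {
    choose(m[1], x) * choose(m[2], k[1] - x) / choose(sum(m), k[1])
  })
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by explicit ranking + product-moment on ranks (handles ties
# through midranks, like cor(method = "spearman"))
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average pairwise difference per site over complete haplotype data:
# haps is a 0/1 matrix (haplotypes x sites); returns sum over sites of the
# mean pairwise difference, i.e. window pi numerator
pi_pairwise_oracle <- function(haps) {
  n <- nrow(haps)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / choose(n, 2)
}

# brute-force overlap decision for two half-open intervals
overlaps_oracle <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)

# random genotype-count configuration for a locus in 2 populations
random_locus <- function() {
  n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
  g1 <- sample(0:2, n1, replace = TRUE)
  g2 <- sample(0:2, n2, replace = TRUE)
  list(n1 = n1, ac1 = sum(g1), het1 = sum(g1 == 1),
       n2 = n2, ac2 = sum(g2), het2 = sum(g2 == 1))
}
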