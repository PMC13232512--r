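#' Per-locus Weir & Cockerham F_ST (two populations)
#'
#' Variance-component estimator theta-hat = a / (a + b + c) of Weir &
#' Cockerham (1984) for a biallelic locus scored in two populations, the
#' quantity vcftools' `--weir-fst-pop` reports per site. Missing genotypes
#' reduce the per-population sample size. The estimator can be negative in
#' finite samples; it is `NA` when the denominator is zero (e.g. a locus
#' monomorphic across both populations).
#'
#' @param n1,n2 genotyped diploid sample sizes per population (>= 2 each for
#'   a defined estimate; loci failing this return `NA`).
#' @param ac1,ac2 alternate allele counts per population (0..2n).
#' @param het1,het2 observed heterozygote counts per population.
#' @return numeric vector of theta-hat values.
#' @export
#' @examples
#' wc_fst(n1 = 20, ac1 = 10, het1 = 6, n2 = 20, ac2 = 25, het2 = 9)
wc_fst <- function(n1, ac1, het1, n2, ac2, het2) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  r <- 2
  p1 <- ac1 / (2 * n1)
  p2 <- ac2 / (2 * n2)
  h1 <- het1 / n1
  h2 <- het2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- a / denom
  theta[!is.finite(theta) | denom == 0] <- NA_real_
  theta[n1 < 2 | n2 < 2] <- NA_real_
  theta
}

#' Add per-SNP F_ST to a genotype-count table
#'
#' @param snps a `snp_table` (or `sv_table` with genotype counts).
#' @return the same table with an `fst` column appended (by reference-safe
#'   copy).
#' @export
add_fst <- function(snps) {
  x <- copy(as.data.table(snps))
  x[, fst := wc_fst(n1, ac1, het1, n2, ac2, het2)]
  x[]
}
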