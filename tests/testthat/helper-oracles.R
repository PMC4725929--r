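# Independent reference computations used to cross-check the package's own
# implementations.  These deliberately take different code paths than the
# functions they verify.

# Conditional-distribution tails through R's negative-binomial CDF: given x,
# the second count is NB(size = x + 1, prob = N1 / (N1 + N2)).
oracle_ac_cdf <- function(y, x, N1, N2) {
  pnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
}

oracle_ac_two_sided <- function(x, y, N1, N2) {
  lower <- oracle_ac_cdf(y, x, N1, N2)
  swapped_lower <- oracle_ac_cdf(x, y, N2, N1)  # = P(Y > y | x)
  min(1, 2 * min(lower, swapped_lower))
}

# Hypergeometric upper tail by direct summation of exact binomial
# coefficients (exact in doubles for N <= 25).
oracle_hyper <- function(N, n, M, m) {
  if (m == 0) return(1)
  i <- 0:(m - 1)
  1 - sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# BH step-up by the textbook construction: sort, cumulative minimum of
# m * p_(j) / j from the largest rank down, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# Amino-acid effect by translating the complete CDS before and after the
# substitution and comparing the protein strings.
oracle_effect <- function(sequence, cds_start, cds_end, pos, alt) {
  cds <- substr(sequence, cds_start, cds_end)
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  mutated <- sequence
  substr(mutated, pos, pos) <- alt
  cds2 <- substr(mutated, cds_start, cds_end)
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds2), no.init.codon = TRUE))
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}
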