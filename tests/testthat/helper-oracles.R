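# Independent oracles used across the suite.

# Gamete dosage distribution of a tetraploid by exhaustive enumeration over
# labeled chromosomes: the non-double-reduction branch enumerates all
# C(4,2) = 6 unordered chromosome pairs; the double-reduction branch
# enumerates the 4 single-chromosome duplications.  Mixture with weight a.
oracle_gamete_tetraploid <- function(dosage, a = 0) {
  chrom <- c(rep(1, dosage), rep(0, 4 - dosage))
  pairs <- utils::combn(4, 2)
  sums_pair <- apply(pairs, 2, function(ix) sum(chrom[ix]))
  p_pair <- tabulate(sums_pair + 1L, nbins = 3L) / ncol(pairs)
  sums_dup <- 2 * chrom
  p_dup <- tabulate(sums_dup + 1L, nbins = 3L) / 4
  (1 - a) * p_pair + a * p_dup
}

# Forced unlike-bivalent duplex gametes: enumerate the 4 equally likely pole
# assignments of the two A-B bivalents.
oracle_forced_duplex <- function() {
  outcomes <- expand.grid(b1 = c(1, 0), b2 = c(1, 0))
  tabulate(outcomes$b1 + outcomes$b2 + 1L, nbins = 3L) / 4
}

# OLS by the normal equations, independent of lm.
oracle_ols <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))
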