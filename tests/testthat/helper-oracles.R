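# Independent O(n) full-scan oracle for the KS running-sum statistics.
# Walks every position i = 0..n of the ranked list and tracks the deviation
# of the query-rank empirical step function from the uniform line; a is the
# maximal positive deviation, b the negated maximal negative deviation.
# Independent of the closed-form max over query positions used in the
# package.
ks_scan_oracle <- function(query_ranks, n) {
  t <- length(query_ranks)
  cnt <- c(0, cumsum(tabulate(query_ranks, n))) # query hits at i = 0..n
  dev <- cnt / t - (0:n) / n
  list(a = max(dev), b = -max(-dev))
}

# random ranked profile over a fresh gene universe
random_ranked_profile <- function(n, id = "c1") {
  genes <- sprintf("g%04d", seq_len(n))
  rank_profile(change_profile(id, genes, stats::rnorm(n)))
}

# gene ids occupying the given ranks of a ranked profile
genes_at_ranks <- function(r, ranks) {
  names(r$rank_of)[match(ranks, r$rank_of)]
}
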