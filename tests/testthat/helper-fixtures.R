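# tiny hand-built alignments used across test files

tiny_alignment <- function() {
  haplotype_alignment(rbind(c(0, 1), c(1, 0), c(1, 1)), c(0.25, 0.75))
}

# random valid alignment for round-trip / property suites
random_alignment <- function(n_rows = NULL, n_cols = NULL) {
  if (is.null(n_rows)) n_rows <- sample(4:12, 1)
  if (is.null(n_cols)) n_cols <- sample(2:15, 1)
  repeat {
    m <- matrix(rbinom(n_rows * n_cols, 1, runif(1, 0.2, 0.8)), n_rows, n_cols)
    cs <- colSums(m)
    if (all(cs > 0 & cs < n_rows)) break
  }
  haplotype_alignment(m, sort(runif(n_cols)))
}

# independent greedy HPD oracle used against the package's Monte Carlo route
greedy_hpd_oracle <- function(p, midpoints, alpha) {
  ord <- order(p, decreasing = TRUE)
  take <- ord[seq_len(which(cumsum(p[ord]) >= 1 - alpha)[1])]
  range(midpoints[take])
}

random_distribution <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

# independent mean-pairwise-difference per column (expected heterozygosity
# of the sample, without replacement)
column_heterozygosity <- function(m) {
  n <- nrow(m)
  i <- colSums(m)
  2 * i * (n - i) / (n * (n - 1))
}
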