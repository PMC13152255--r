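# Shared fixtures and independent oracles for cross-checking.

fixture <- function(name) {
  path <- system.file("extdata", name, package = "sgecurate")
  stopifnot(nzchar(path))
  path
}

table1 <- function() read_variant_table(fixture("table1.tsv"))
table2 <- function() read_variant_table(fixture("table2.tsv"))

# closed-form Bhapkar statistic for a 2x2 table (McNemar with the
# marginal-difference correction); independent of the matrix-algebra path
bhapkar_2x2_oracle <- function(tab) {
  n <- sum(tab)
  diff <- tab[1, 2] - tab[2, 1]
  denom <- tab[1, 2] + tab[2, 1] - diff^2 / n
  if (denom == 0) 0 else diff^2 / denom
}

# parametric-bootstrap p-value: resample paired tables from the symmetrized
# cell probabilities (the closest null of marginal homogeneity) and compare
# the observed statistic with the resampled distribution
bhapkar_bootstrap_p <- function(tab, B = 10000) {
  n <- sum(tab)
  k <- nrow(tab)
  p0 <- (tab + t(tab)) / (2 * n)
  obs <- bhapkar_test(tab)$statistic
  draws <- stats::rmultinom(B, n, as.vector(p0))
  stats_b <- apply(draws, 2, function(v) {
    bhapkar_test(matrix(v, k, k))$statistic
  })
  mean(stats_b >= obs)
}

random_pair_table <- function(k, n, concentrate = 1) {
  probs <- stats::rgamma(k * k, shape = concentrate)
  matrix(as.vector(stats::rmultinom(1, n, probs / sum(probs))), k, k)
}

# exact binomial 99% central interval for an observed proportion
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p) / n

class_rank <- function(label) match(label, class_levels())
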