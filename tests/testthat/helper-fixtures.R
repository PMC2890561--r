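# Shared fixtures and independent oracles used across test files.

# n times the joint genotype probability table (fractional cells allowed)
expectation_counts <- function(p, q, D, n = 200) {
  genotype_counts(n * unclass(joint_probs(ld_params(p, q, D))))
}

# expectation counts under Scheme II truncation (renormalized)
expectation_counts_scheme2 <- function(p, q, D, excluded, n = 200) {
  P <- unclass(joint_probs(ld_params(p, q, D)))
  P[ldnr:::.excluded_mask(excluded)] <- 0
  genotype_counts(n * P / sum(P))
}

# expectation counts for a Scheme III case-control design
expectation_counts_scheme3 <- function(p, q, D, n_case, n_control) {
  g <- haplotype_freqs(ld_params(p, q, D))
  pMA <- g[["g11"]] / q
  pMa <- g[["g12"]] / (1 - q)
  cases <- matrix(0, 3, 3)
  wAA <- q / (2 - q)
  cases[, 1] <- n_case * wAA * c(pMA^2, 2 * pMA * (1 - pMA), (1 - pMA)^2)
  cases[, 2] <- n_case * (1 - wAA) *
    c(pMA * pMa, pMA * (1 - pMa) + (1 - pMA) * pMa, (1 - pMA) * (1 - pMa))
  ctrl <- matrix(0, 3, 3)
  ctrl[, 3] <- n_control * c(pMa^2, 2 * pMa * (1 - pMa), (1 - pMa)^2)
  list(cases = genotype_counts(cases), controls = genotype_counts(ctrl),
       combined = genotype_counts(cases + ctrl))
}

# random feasible parameter draw (away from degenerate corners)
random_params <- function() {
  p <- runif(1, 0.05, 0.95)
  q <- runif(1, 0.05, 0.95)
  b <- d_bounds(p, q)
  ld_params(p, q, runif(1, 0.9 * b[[1]], 0.9 * b[[2]]))
}

# random genotype count table from a random population (Scheme I draw)
random_counts <- function(n = 200) {
  pp <- random_params()
  list(params = pp, counts = sample_scheme1(pp, n))
}

# Independent grid-search oracle for the conditional MLE: no refinement, no
# score polishing -- just a dense evaluation of the log-likelihood.
grid_mle_conditional <- function(counts, p, q, K = 20001) {
  b <- d_bounds(p, q)
  grid <- seq(b[[1]] + 1e-9, b[[2]] - 1e-9, length.out = K)
  ll <- loglik_conditional(counts, p, q, grid)
  i <- which.max(ll)
  list(D = grid[i], loglik = ll[i])
}

# Same oracle for the joint likelihood over g11.
grid_mle_joint <- function(counts, p, q, K = 20001) {
  gb <- g11_bounds(p, q)
  grid <- seq(gb[[1]] + 1e-9, gb[[2]] - 1e-9, length.out = K)
  ll <- loglik_joint(counts, p, q, grid)
  i <- which.max(ll)
  list(g11 = grid[i], loglik = ll[i])
}

# Brute-force conditional log-likelihood: explicit double loop over cells.
bruteforce_loglik_conditional <- function(counts, p, q, D) {
  f <- conditional_probs(ld_params(p, q, D))
  tot <- 0
  for (i in 1:3) for (j in 1:3) {
    n_ij <- counts[i, j]
    if (n_ij > 0) tot <- tot + n_ij * log(f[i, j])
  }
  tot
}

# allele-relabel helpers (swap marker allele M <-> m)
swap_marker <- function(counts) genotype_counts(unclass(counts)[3:1, ])
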