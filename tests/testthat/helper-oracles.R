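## Independent oracles used across the suite.

## Exhaustive enumeration of the distribution of a sum of k iid cluster
## counts: loops over all (m+1)^k ordered outcome tuples. Only usable at
## tiny sizes, which is the point -- it shares no code with convolve_iid().
enumerate_total_pmf <- function(cluster_probs, k) {
  m <- length(cluster_probs) - 1L
  grid <- expand.grid(rep(list(0:m), k))
  probs <- numeric(k * m + 1L)
  for (i in seq_len(nrow(grid))) {
    counts <- as.integer(grid[i, ])
    probs[sum(counts) + 1L] <- probs[sum(counts) + 1L] +
      prod(cluster_probs[counts + 1L])
  }
  probs
}

## Beta-binomial pmf by numerical integration over the latent coverage,
## independent of the closed-form beta-function route in the package.
bb_pmf_by_integration <- function(m, p, rho) {
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  vapply(0:m, function(x) {
    stats::integrate(function(q) stats::dbinom(x, m, q) * stats::dbeta(q, a, b),
                     0, 1, rel.tol = 1e-10)$value
  }, numeric(1))
}

## Brute-force rule search on binomial pmfs: checks every d directly.
brute_force_feasible_d <- function(n, p_l, p_u, alpha, beta) {
  for (d in 0:n) {
    if (pbinom(d, n, p_u) <= alpha &&
        pbinom(d, n, p_l, lower.tail = FALSE) <= beta)
      return(d)
  }
  NULL
}

## The three threshold couplets used throughout the published comparisons.
example_couplets <- function() {
  list(design_targets(0.55, 0.70),
       design_targets(0.75, 0.90),
       design_targets(0.90, 0.95))
}

## Tolerance for comparing an exact or simulated risk against a published
## value that was itself estimated from n_sims Monte-Carlo draws.
mc_tol <- function(r, n_sims = 10000, n_se = 3) n_se * sqrt(r * (1 - r) / n_sims)
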