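test_that("beta-binomial cluster pmf has the stated moments and limits", {
  pmf <- betabinomial_pmf(10, 0.7, 0.05)
  expect_equal(sum(pmf$probs), 1, tolerance = 1e-9)
  expect_true(all(pmf$probs >= 0))
  expect_equal(pmf_mean(pmf), 7)
  expect_equal(pmf_variance(pmf), 10 * 0.21 * (1 + 9 * 0.05), tolerance = 1e-9)
  ## agrees with numerical integration over the latent beta coverage
  expect_equal(pmf$probs, bb_pmf_by_integration(10, 0.7, 0.05),
               tolerance = 1e-8)
  ## vanishing-clustering limit is the plain binomial
  expect_equal(betabinomial_pmf(8, 0.4, 1e-8)$probs, dbinom(0:8, 8, 0.4),
               tolerance = 1e-6)
  expect_equal(betabinomial_pmf(8, 0.4, 0)$probs, dbinom(0:8, 8, 0.4))
  ## full clustering: whole cluster succeeds or fails together
  expect_equal(betabinomial_pmf(5, 0.3, 1)$probs, c(0.7, 0, 0, 0, 0, 0.3))
})

test_that("binomial-scaled cluster pmf is the lattice mixture it claims to be", {
  ## eta = 1: coverage is 0 or 1, so the cluster count is 0 or m
  pmf <- binomial_scaled_pmf(7, 0.35, 1)
  expect_equal(pmf$probs[c(1, 8)], c(0.65, 0.35))
  expect_equal(sum(pmf$probs), 1, tolerance = 1e-12)
  ## mean m*p for any eta; variance m p(1-p) (1 + (m-1)/eta)
  for (eta in c(2, 9, 21)) {
    pmf <- binomial_scaled_pmf(10, 0.7, eta)
    expect_equal(pmf_mean(pmf), 7, tolerance = 1e-9)
    expect_equal(pmf_variance(pmf), 10 * 0.21 * (1 + 9 / eta),
                 tolerance = 1e-9)
  }
})

test_that("iid convolution reproduces closed forms and exhaustive enumeration", {
  ## k = 1 is the identity
  base <- betabinomial_pmf(4, 0.6, 0.15)
  expect_equal(convolve_iid(base, 1)$probs, base$probs)
  ## Bernoulli clusters convolve to the binomial
  bern <- total_pmf(c(0.3, 0.7))
  expect_equal(convolve_iid(bern, 2)$probs, dbinom(0:2, 2, 0.7))
  expect_equal(convolve_iid(bern, 9)$probs, dbinom(0:9, 9, 0.7),
               tolerance = 1e-12)
  ## beta-binomial m = 2, k = 3 against brute-force enumeration of all
  ## 27 ordered cluster-outcome triples
  cl <- betabinomial_pmf(2, 0.6, 0.2)
  expect_equal(convolve_iid(cl, 3)$probs, enumerate_total_pmf(cl$probs, 3),
               tolerance = 1e-12)
})

test_that("binomial risks match the published SRS evaluations", {
  expect_equal(round(binomial_risks(71, 44, 0.55, 0.70), 3),
               c(alpha = 0.091, beta = 0.096))
  expect_equal(round(binomial_risks(40, 33, 0.75, 0.90), 3),
               c(alpha = 0.100, beta = 0.096))
  r <- binomial_risks(25, 25, 0.55, 0.70)
  expect_equal(r, c(alpha = 1, beta = 0))  # d = n classifies everything low
  expect_error(binomial_risks(25, 26, 0.55, 0.70), class = "clqas_usage_error")
})

test_that("model risks reproduce the published cluster design evaluations", {
  ## quasi-binomial rows are exact after effective-scale rounding
  r <- model_risks("hund", k = 8, m = 10, d = 66,
                   targets = design_targets(0.75, 0.90),
                   clustering = clustering_spec(rho = 0.11))
  expect_equal(round(r, 3), c(alpha = 0.100, beta = 0.096))
  expect_equal(r, binomial_risks(40, 33, 0.75, 0.90))  # the effective image
  ## beta-binomial rows were published from 10^4-draw simulations, so the
  ## exact convolution must sit within their Monte-Carlo resolution
  r <- model_risks("hedt", k = 11, m = 10, d = 68,
                   targets = design_targets(0.55, 0.70),
                   clustering = clustering_spec(rho = 0.04))
  expect_lt(abs(r[["alpha"]] - 0.071), mc_tol(0.071))
  expect_lt(abs(r[["beta"]] - 0.097), mc_tol(0.097))
  r <- model_risks("hedt", k = 9, m = 10, d = 75,
                   targets = design_targets(0.75, 0.90),
                   clustering = clustering_spec(rho = 0.1))
  expect_lt(abs(r[["alpha"]] - 0.088), mc_tol(0.088))
  expect_lt(abs(r[["beta"]] - 0.073), mc_tol(0.073))
  ## binomial-scaled row, same Monte-Carlo comparison
  r <- model_risks("pezzoli", k = 10, m = 10, d = 62,
                   targets = design_targets(0.55, 0.70),
                   clustering = clustering_spec(sigma = 0.1))
  expect_lt(abs(r[["alpha"]] - 0.090), mc_tol(0.090))
  expect_lt(abs(r[["beta"]] - 0.096), mc_tol(0.096))
})

test_that("a failure-count rule is the mirrored success rule", {
  expect_equal(failure_to_success_rule(198, 13), 184)
  tg <- design_targets(0.90, 0.95)
  cl <- clustering_spec(sigma = 0.1)
  for (mt in c("srs", "pezzoli", "hedt")) {
    expect_equal(
      model_risks(mt, 33, 6, 13, tg, cl, scale = "failures"),
      model_risks(mt, 33, 6, 184, tg, cl))
  }
  ## for the quasi-binomial model the rounding scale matters, so the two
  ## routes legitimately differ
  r_fail <- model_risks("hund", 33, 6, 13, tg, clustering_spec(rho = 0.1),
                        scale = "failures")
  expect_equal(round(r_fail[["beta"]], 3), 0.139)
})

test_that("risks are monotone in d and converge to binomial as clustering vanishes", {
  tg <- design_targets(0.75, 0.90)
  tiny <- clustering_spec(rho = 1e-6)
  some <- clustering_spec(rho = 0.08)
  for (mt in c("srs", "pezzoli", "hedt", "hund")) {
    risks <- vapply(seq(0, 60, by = 5), function(d)
      model_risks(mt, 6, 10, d, tg, some), numeric(2))
    expect_true(all(diff(risks["alpha", ]) >= 0))
    expect_true(all(diff(risks["beta", ]) <= 0))
    expect_equal(model_risks(mt, 6, 10, 50, tg, tiny),
                 binomial_risks(60, 50, 0.75, 0.90), tolerance = 1e-4)
  }
})

test_that("variance ordering: clustering inflates the convolved total", {
  k <- 6; m <- 10; p <- 0.7; rho <- 0.1
  tot <- convolve_iid(betabinomial_pmf(m, p, rho), k)
  expect_equal(pmf_mean(tot), k * m * p, tolerance = 1e-6)
  expect_equal(pmf_variance(tot), k * m * p * (1 - p) * (1 + (m - 1) * rho),
               tolerance = 1e-6)
  expect_gt(pmf_variance(tot), k * m * p * (1 - p))  # above the binomial
})

test_that("samplers agree with the exact distributions", {
  cl <- clustering_spec(sigma = 0.1)
  set.seed(4)
  ## two-stage beta draws center on kmp
  x <- sample_total("hedt", 6, 10, 0.7, cl, n_draws = 10000)
  se <- sqrt(pmf_variance(convolve_iid(betabinomial_pmf(10, 0.7,
    rho_from_sigma(0.1, 0.7)), 6)) / 10000)
  expect_lt(abs(mean(x) - 42), 3 * se)
  ## no-clustering limit collapses every sampler onto the binomial
  none <- clustering_spec(sigma = 0)
  for (mt in c("pezzoli", "hedt", "hund")) {
    y <- sample_total(mt, 4, 5, 0.6, none, n_draws = 5000)
    emp <- tabulate(y + 1L, nbins = 21) / 5000
    expect_lt(0.5 * sum(abs(emp - dbinom(0:20, 20, 0.6))), 0.05)
  }
  ## binomial-scaled empirical law vs the exact finite mixture
  x <- sample_total("pezzoli", 6, 10, 0.7, cl, n_draws = 20000)
  emp <- tabulate(x + 1L, nbins = 61) / 20000
  exact <- convolve_iid(binomial_scaled_pmf(10, 0.7, 21), 6)$probs
  expect_lt(0.5 * sum(abs(emp - exact)), 0.05)
  ## latent draws expose the two-stage structure
  sim <- sample_total("hedt", 5, 8, 0.75, cl, n_draws = 3, latent = TRUE)
  expect_equal(dim(sim$counts), c(5, 3))
  expect_equal(colSums(sim$counts), sim$totals)
  expect_true(all(sim$coverages >= 0 & sim$coverages <= 1))
})
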