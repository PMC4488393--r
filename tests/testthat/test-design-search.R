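test_that("feasible-rule search agrees with brute force on binomial pmfs", {
  tg <- design_targets(0.55, 0.70)
  pmf_at <- function(n, p) total_pmf(dbinom(0:n, n, p))
  fit <- find_feasible_d(pmf_at(71, 0.55), pmf_at(71, 0.70), tg)
  expect_equal(fit$d, 44)
  expect_equal(fit$d, brute_force_feasible_d(71, 0.55, 0.70, 0.1, 0.1))
  expect_true(fit$interval[1] <= 44 && 44 <= fit$interval[2])
  ## too small a sample: no rule can work
  expect_null(find_feasible_d(pmf_at(10, 0.55), pmf_at(10, 0.70), tg))
  expect_null(brute_force_feasible_d(10, 0.55, 0.70, 0.1, 0.1))
  ## caps so lax they never bind accept the smallest rule
  lax <- design_targets(0.55, 0.70, alpha = 0.9999, beta = 0.9999)
  expect_equal(find_feasible_d(pmf_at(10, 0.55), pmf_at(10, 0.70), lax)$d, 0)
})

test_that("minimal SRS designs match the published binomial search", {
  expected <- list(
    list(tg = design_targets(0.55, 0.70), n = 71, d = 44,
         risks = c(0.091, 0.096)),
    list(tg = design_targets(0.75, 0.90), n = 40, d = 33,
         risks = c(0.100, 0.096)),
    list(tg = design_targets(0.90, 0.95), n = 187, d = 173,
         risks = c(0.087, 0.098)))
  for (case in expected) {
    des <- find_srs_design(case$tg)
    expect_equal(des$n, case$n)
    expect_equal(des$d, case$d)
    expect_equal(round(c(des$alpha, des$beta), 3), case$risks)
  }
})

test_that("minimal-k beta-binomial searches reproduce the published sample sizes", {
  cl <- clustering_spec(rho = 0.1)
  des <- find_cluster_design("hedt", design_targets(0.75, 0.90), cl, m = 10)
  expect_equal(c(des$n, des$d, des$k), c(90, 75, 9))
  expect_lt(abs(des$alpha - 0.088), mc_tol(0.088))
  expect_lt(abs(des$beta - 0.073), mc_tol(0.073))
  des <- find_cluster_design("hedt", design_targets(0.90, 0.95), cl, m = 10)
  expect_equal(c(des$n, des$d), c(370, 343))
  des <- find_cluster_design("hedt", design_targets(0.55, 0.70), cl, m = 10)
  expect_equal(c(des$n, des$d), c(140, 87))
})

test_that("without clustering the cluster search is the SRS design in whole clusters", {
  none <- clustering_spec(rho = 0)
  tg <- design_targets(0.55, 0.70)
  for (mt in c("pezzoli", "hedt", "hund")) {
    des <- find_cluster_design(mt, tg, none, m = 10)
    expect_equal(des$k, 8)                     # ceil(71 / 10)
    expect_equal(model_risks(mt, des$k, des$m, des$d, tg, none),
                 binomial_risks(80, des$d, 0.55, 0.70))
  }
})

test_that("fixed-k searches grow m and respect the SRS floor", {
  tg <- design_targets(0.75, 0.90)
  ## binomial feasibility is not monotone in n (42 and 48 admit no rule
  ## for this couplet), so the first feasible multiple of 6 is 54
  des <- find_cluster_design_fixed_k("hedt", tg, clustering_spec(rho = 0),
                                     k = 6)
  ms <- vapply(7:9, function(m)
    !is.null(brute_force_feasible_d(6 * m, 0.75, 0.90, 0.1, 0.1)),
    logical(1))
  expect_equal(des$m, (7:9)[ms][1])
  expect_equal(c(des$m, des$n), c(9, 54))
  des <- find_cluster_design_fixed_k("hedt", tg, clustering_spec(rho = 0.1),
                                     k = 6)
  expect_gte(des$n, 40)
  ## the published k = 6 envelope for sigma = .1 at the 75-90% couplet
  for (mt in c("pezzoli", "hedt", "hund")) {
    des <- find_cluster_design_fixed_k(mt, tg, clustering_spec(sigma = 0.1),
                                       k = 6)
    expect_gte(des$n, 72)
    expect_lte(des$n, 150)
  }
})

test_that("the effective-sample-size search matches the published geometry", {
  des <- hund_design(design_targets(0.75, 0.90), clustering_spec(rho = 0.11),
                     m = 10)
  expect_equal(des$n, 80)
  ## the published rule 66 sits in the feasible interval; the smallest
  ## rule with the same effective image (and identical risks) is returned
  expect_true(des$d_interval[1] <= 66 && 66 <= des$d_interval[2])
  expect_equal(model_risks("hund", 8, 10, des$d, des$targets, des$clustering),
               model_risks("hund", 8, 10, 66, des$targets, des$clustering))
  expect_equal(round(c(des$alpha, des$beta), 3), c(0.100, 0.096))
  ## no clustering: identical to SRS rounded up to whole clusters
  des0 <- hund_design(design_targets(0.55, 0.70), clustering_spec(rho = 0),
                      m = 10)
  expect_equal(des0$n, 80)
})

test_that("binomial-scaled searches agree between exact and simulation modes", {
  cl <- clustering_spec(sigma = 0.1)
  des <- pezzoli_design(design_targets(0.75, 0.90), cl, m = 10)
  expect_equal(c(des$n, des$d, des$k), c(80, 66, 8))
  expect_lt(abs(des$alpha - 0.088), mc_tol(0.088))
  expect_lt(abs(des$beta - 0.076), mc_tol(0.076))
  for (tg in list(design_targets(0.55, 0.70), design_targets(0.75, 0.90))) {
    exact <- pezzoli_design(tg, cl, m = 10)
    sim <- pezzoli_design(tg, cl, m = 10, mode = "simulate", n_sims = 1e5,
                          seed = 1)
    expect_equal(c(sim$n, sim$d), c(exact$n, exact$d))
  }
})

test_that("searches are monotone in clustering and never beat SRS", {
  tg <- design_targets(0.75, 0.90)
  n_srs <- find_srs_design(tg)$n
  n_prev <- 0
  for (rho in c(0, 0.05, 0.1, 0.2)) {
    des <- find_cluster_design("hedt", tg, clustering_spec(rho = rho), m = 10)
    expect_gte(des$n, n_prev)
    expect_gte(des$n, n_srs)
    expect_lte(des$alpha, tg$alpha)
    expect_lte(des$beta, tg$beta)
    n_prev <- des$n
  }
  ## larger clusters inflate the design effect, hence the required n
  n_by_m <- vapply(c(5, 10, 15), function(m)
    find_cluster_design("hedt", tg, clustering_spec(rho = 0.1), m = m)$n,
    numeric(1))
  expect_true(all(diff(n_by_m) >= 0))
})

test_that("cost minimization agrees with exhaustive evaluation of the grid", {
  tg <- design_targets(0.75, 0.90)
  cl <- clustering_spec(rho = 0.1)
  grid <- c(5, 10, 15)
  best <- cost_optimal_design("hedt", tg, cl, cost_per_cluster = 10,
                              cost_per_subject = 1, m_grid = grid)
  costs <- vapply(grid, function(m) {
    d <- find_cluster_design("hedt", tg, cl, m = m)
    d$k * 10 + d$n * 1
  }, numeric(1))
  expect_equal(best$m, grid[which.min(costs)])
  expect_equal(best$cost, min(costs))
  ## free clusters: minimize n alone
  free <- cost_optimal_design("hedt", tg, cl, 0, 1, m_grid = grid)
  ns <- vapply(grid, function(m) find_cluster_design("hedt", tg, cl, m)$n,
               numeric(1))
  expect_equal(free$n, min(ns))
  ## degenerate grid reduces to the fixed-m search
  one <- cost_optimal_design("hedt", tg, cl, 10, 1, m_grid = 10)
  ten <- find_cluster_design("hedt", tg, cl, m = 10)
  expect_equal(c(one$n, one$d), c(ten$n, ten$d))
})

test_that("search caps raise classed infeasibility errors", {
  tight <- design_targets(0.50, 0.52, alpha = 0.01, beta = 0.01)
  expect_error(find_srs_design(tight, n_max = 50),
               class = "clqas_infeasible")
  expect_error(find_cluster_design("hedt", design_targets(0.90, 0.95),
                                   clustering_spec(rho = 0.1), m = 10,
                                   k_max = 5),
               class = "clqas_infeasible")
})

test_that("single-cluster designs carry a warning", {
  lax <- design_targets(0.3, 0.9, alpha = 0.5, beta = 0.5)
  expect_warning(
    find_cluster_design("hedt", lax, clustering_spec(rho = 0.05), m = 10),
    "single cluster")
})
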