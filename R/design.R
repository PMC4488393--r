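#' Feasible decision rules given total distributions at both thresholds
#'
#' Scans all candidate rules `d = 0..n` against the exact distributions
#' of the survey total at the two thresholds and returns the smallest
#' `d` whose risks respect both caps, together with the full feasible
#' interval (risk curves are monotone in `d`, so the feasible set is an
#' interval).
#'
#' @param pmf_l,pmf_u [total_pmf()] objects for the survey total at
#'   `p_l` and `p_u`; they must share the same support.
#' @param targets An [design_targets()] object.
#' @return `NULL` when no rule is feasible; otherwise a list with the
#'   smallest feasible `d`, its achieved `alpha` and `beta`, and the
#'   feasible `interval` `c(lo, hi)`.
#' @examples
#' tg <- design_targets(0.55, 0.70)
#' find_feasible_d(total_pmf(dbinom(0:71, 71, 0.55)),
#'                 total_pmf(dbinom(0:71, 71, 0.70)), tg)
#' @export
find_feasible_d <- function(pmf_l, pmf_u, targets) {
  stopifnot(inherits(targets, "lqas_targets"))
  pl <- pmf_probs(pmf_l); pu <- pmf_probs(pmf_u)
  if (length(pl) != length(pu))
    abort_usage("the two pmfs must share the same support 0..n")
  alpha_d <- cumsum(pu)            # P(X <= d | p_u), d = 0..n
  beta_d <- 1 - cumsum(pl)         # P(X >  d | p_l)
  ok <- which(alpha_d <= targets$alpha & beta_d <= targets$beta)
  if (length(ok) == 0L) return(NULL)
  d <- ok[1L] - 1L
  list(d = d, alpha = alpha_d[ok[1L]], beta = beta_d[ok[1L]],
       interval = c(ok[1L], ok[length(ok)]) - 1L)
}

## feasibility for the quasi-binomial model: risks are step functions of
## the effective image of d, so scan d = 0..n through effective_count()
hund_feasible_d <- function(n, m, targets, clustering) {
  D_l <- design_effect(m, rho_at(clustering, targets$p_l))
  D_u <- design_effect(m, rho_at(clustering, targets$p_u))
  d <- 0:n
  alpha_d <- stats::pbinom(effective_count(d, D_u), effective_count(n, D_u),
                           targets$p_u)
  beta_d <- stats::pbinom(effective_count(d, D_l), effective_count(n, D_l),
                          targets$p_l, lower.tail = FALSE)
  ok <- which(alpha_d <= targets$alpha & beta_d <= targets$beta)
  if (length(ok) == 0L) return(NULL)
  list(d = d[ok[1L]], alpha = alpha_d[ok[1L]], beta = beta_d[ok[1L]],
       interval = c(d[ok[1L]], d[ok[length(ok)]]))
}

#' Minimal simple-random-sampling LQAS design
#'
#' Scans total sample sizes `n = 1, 2, ...` under the binomial model and
#' returns the smallest `n` admitting a feasible decision rule, with the
#' smallest such rule.
#'
#' @param targets An [design_targets()] object.
#' @param n_max Search cap; exceeding it raises an infeasibility error.
#' @return A `"cluster_design"` object with `method = "srs"`.
#' @examples
#' find_srs_design(design_targets(0.55, 0.70))  # n = 71, d = 44
#' @export
find_srs_design <- function(targets, n_max = 10000) {
  stopifnot(inherits(targets, "lqas_targets"))
  for (n in seq_len(n_max)) {
    d <- 0:n
    alpha_d <- stats::pbinom(d, n, targets$p_u)
    beta_d <- stats::pbinom(d, n, targets$p_l, lower.tail = FALSE)
    ok <- which(alpha_d <= targets$alpha & beta_d <= targets$beta)
    if (length(ok)) {
      return(new_cluster_design("srs", k = NA_integer_, m = NA_integer_,
                                n = n, d = ok[1L] - 1L,
                                alpha = alpha_d[ok[1L]], beta = beta_d[ok[1L]],
                                targets = targets, clustering = NULL))
    }
  }
  abort_infeasible(sprintf("no feasible SRS design with n <= %d", n_max))
}

#' Minimal cluster LQAS design with fixed within-cluster size
#'
#' Adds clusters one at a time (fixed `m`) and returns the first
#' geometry admitting a feasible decision rule under the requested
#' model, evaluated exactly. Clustering is resolved at each threshold
#' from `clustering`, so a fixed-`sigma` specification induces different
#' `rho` (and `eta`) at `p_l` and `p_u`, and conversely.
#'
#' @param method `"srs"`, `"pezzoli"`, `"hedt"` or `"hund"`.
#' @param targets An [design_targets()] object.
#' @param clustering An [clustering_spec()] object.
#' @param m Within-cluster sample size, held fixed.
#' @param k_max Cap on the number of clusters.
#' @return A `"cluster_design"` object; its achieved risks satisfy the
#'   caps by construction.
#' @examples
#' find_cluster_design("hedt", design_targets(0.75, 0.90),
#'                     clustering_spec(rho = 0.1), m = 10)  # n = 90, d = 75
#' @export
find_cluster_design <- function(method, targets, clustering, m, k_max = 2000) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  stopifnot(inherits(targets, "lqas_targets"), m >= 1)
  ## running convolutions avoid rebuilding the total pmf at every k
  run_l <- run_u <- 1
  if (method %in% c("pezzoli", "hedt", "srs")) {
    cl_l <- cluster_total_pmf(method, 1, m, targets$p_l, clustering)
    cl_u <- cluster_total_pmf(method, 1, m, targets$p_u, clustering)
  }
  for (k in seq_len(k_max)) {
    if (method == "hund") {
      fit <- hund_feasible_d(k * m, m, targets, clustering)
    } else {
      run_l <- conv_pair(run_l, cl_l$probs)
      run_u <- conv_pair(run_u, cl_u$probs)
      fit <- find_feasible_d(total_pmf(run_l), total_pmf(run_u), targets)
    }
    if (!is.null(fit)) {
      if (k == 1L)
        warning("design uses a single cluster; real surveys need k >= 2",
                call. = FALSE)
      return(new_cluster_design(method, k = k, m = m, n = k * m, d = fit$d,
                                alpha = fit$alpha, beta = fit$beta,
                                targets = targets, clustering = clustering,
                                d_interval = fit$interval))
    }
  }
  abort_infeasible(sprintf("no feasible %s design with k <= %d", method, k_max))
}

#' Minimal cluster LQAS design with fixed cluster count
#'
#' Holds the number of clusters fixed and grows the within-cluster
#' sample size until a feasible rule exists. Because the design effect
#' grows with `m`, feasibility is re-evaluated model-exactly at every
#' step rather than scaled from the SRS design.
#'
#' @inheritParams find_cluster_design
#' @param k Number of clusters, held fixed.
#' @param m_max Cap on the within-cluster sample size.
#' @return A `"cluster_design"` object.
#' @examples
#' find_cluster_design_fixed_k("hedt", design_targets(0.75, 0.90),
#'                             clustering_spec(rho = 0.1), k = 6)
#' @export
find_cluster_design_fixed_k <- function(method, targets, clustering, k,
                                        m_max = 500) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  stopifnot(inherits(targets, "lqas_targets"), k >= 1)
  for (m in seq_len(m_max)) {
    fit <- if (method == "hund") {
      hund_feasible_d(k * m, m, targets, clustering)
    } else {
      find_feasible_d(cluster_total_pmf(method, k, m, targets$p_l, clustering),
                      cluster_total_pmf(method, k, m, targets$p_u, clustering),
                      targets)
    }
    if (!is.null(fit))
      return(new_cluster_design(method, k = k, m = m, n = k * m, d = fit$d,
                                alpha = fit$alpha, beta = fit$beta,
                                targets = targets, clustering = clustering,
                                d_interval = fit$interval))
  }
  abort_infeasible(sprintf("no feasible %s design with m <= %d", method, m_max))
}

#' Quasi-binomial (effective sample size) design search
#'
#' Convenience wrapper: the quasi-binomial construction calculates the
#' design under SRS on the effective scale and inflates by the design
#' effect; operationally this is [find_cluster_design()] with
#' `method = "hund"`, which scans whole clusters and picks the smallest
#' original-scale rule whose effective image is feasible.
#'
#' @inheritParams find_cluster_design
#' @return A `"cluster_design"` object.
#' @examples
#' hund_design(design_targets(0.75, 0.90), clustering_spec(rho = 0.11),
#'             m = 10)  # n = 80, d = 66
#' @export
hund_design <- function(targets, clustering, m, k_max = 2000) {
  find_cluster_design("hund", targets, clustering, m, k_max = k_max)
}

#' Binomial-scaled (Pezzoli) design search
#'
#' Searches the minimal whole-cluster design under the binomial-scaled
#' model. By default risks are evaluated from the exact finite-mixture
#' pmf (the lattice coverage distribution has `eta + 1` support points,
#' so no simulation is required). `mode = "simulate"` reproduces the
#' historical simulation-based workflow with `n_sims` seeded draws per
#' threshold at every candidate geometry.
#'
#' @inheritParams find_cluster_design
#' @param mode `"exact"` (default) or `"simulate"`.
#' @param n_sims Draws per threshold in simulation mode.
#' @param seed Optional seed applied once before the simulation search.
#' @return A `"cluster_design"` object.
#' @examples
#' pezzoli_design(design_targets(0.75, 0.90), clustering_spec(sigma = 0.1),
#'                m = 10)  # n = 80, d = 66
#' @export
pezzoli_design <- function(targets, clustering, m, k_max = 2000,
                           mode = c("exact", "simulate"), n_sims = 10000,
                           seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact")
    return(find_cluster_design("pezzoli", targets, clustering, m, k_max = k_max))
  if (!is.null(seed)) set.seed(seed)
  if (n_sims < 1) abort_usage("'n_sims' must be at least 1")
  for (k in seq_len(k_max)) {
    n <- k * m
    x_l <- sample_total("pezzoli", k, m, targets$p_l, clustering, n_draws = n_sims)
    x_u <- sample_total("pezzoli", k, m, targets$p_u, clustering, n_draws = n_sims)
    emp_l <- tabulate(x_l + 1L, nbins = n + 1L) / n_sims
    emp_u <- tabulate(x_u + 1L, nbins = n + 1L) / n_sims
    fit <- find_feasible_d(total_pmf(emp_l), total_pmf(emp_u), targets)
    if (!is.null(fit)) {
      des <- new_cluster_design("pezzoli", k = k, m = m, n = n, d = fit$d,
                                alpha = fit$alpha, beta = fit$beta,
                                targets = targets, clustering = clustering,
                                d_interval = fit$interval, check_caps = FALSE)
      des$evaluation <- "simulate"
      des$n_sims <- n_sims
      return(des)
    }
  }
  abort_infeasible(sprintf("no feasible pezzoli design with k <= %d", k_max))
}

#' Cost-minimizing cluster LQAS design
#'
#' Iterates over candidate within-cluster sizes, finds the minimal
#' feasible design for each, and returns the design minimizing total
#' field cost `k * cost_per_cluster + n * cost_per_subject`. Ties are
#' broken toward smaller `n`, then smaller `m`.
#'
#' @inheritParams find_cluster_design
#' @param cost_per_cluster Cost of visiting one cluster (>= 0).
#' @param cost_per_subject Cost of sampling one subject (>= 0).
#' @param m_grid Candidate within-cluster sample sizes.
#' @return The cost-minimizing `"cluster_design"`, with a `cost` field;
#'   the full grid of candidates is attached as the `"candidates"`
#'   attribute.
#' @examples
#' cost_optimal_design("hedt", design_targets(0.75, 0.90),
#'                     clustering_spec(rho = 0.1),
#'                     cost_per_cluster = 10, cost_per_subject = 1,
#'                     m_grid = c(5, 10, 15))
#' @export
cost_optimal_design <- function(method, targets, clustering, cost_per_cluster,
                                cost_per_subject, m_grid, k_max = 2000) {
  if (length(m_grid) == 0L) abort_usage("'m_grid' must be non-empty")
  if (cost_per_cluster < 0 || cost_per_subject < 0)
    abort_usage("costs must be non-negative")
  candidates <- list()
  for (m in m_grid) {
    des <- tryCatch(
      find_cluster_design(method, targets, clustering, m, k_max = k_max),
      clqas_infeasible = function(e) NULL)
    if (!is.null(des)) {
      des$cost <- des$k * cost_per_cluster + des$n * cost_per_subject
      candidates[[length(candidates) + 1L]] <- des
    }
  }
  if (length(candidates) == 0L)
    abort_infeasible("no feasible design for any m in 'm_grid'")
  cost <- vapply(candidates, `[[`, numeric(1), "cost")
  nn <- vapply(candidates, `[[`, numeric(1), "n")
  mm <- vapply(candidates, `[[`, numeric(1), "m")
  best <- order(cost, nn, mm)[1L]
  out <- candidates[[best]]
  attr(out, "candidates") <- do.call(rbind, lapply(candidates, as.data.frame))
  out
}

## ---- design container -------------------------------------------------

new_cluster_design <- function(method, k, m, n, d, alpha, beta, targets,
                               clustering, d_interval = c(d, d),
                               check_caps = TRUE) {
  if (check_caps && (alpha > targets$alpha + 1e-12 || beta > targets$beta + 1e-12))
    stop("internal error: returned design violates the risk caps")
  des <- list(method = method, k = k, m = m, n = n, d = d,
              alpha = alpha, beta = beta, targets = targets,
              clustering = clustering, d_interval = d_interval,
              evaluation = "exact")
  if (!is.null(clustering)) {
    des$rho_l <- rho_at(clustering, targets$p_l)
    des$rho_u <- rho_at(clustering, targets$p_u)
    des$sigma_l <- sigma_at(clustering, targets$p_l)
    des$sigma_u <- sigma_at(clustering, targets$p_u)
    if (method == "pezzoli" && des$sigma_l > 0) {
      des$eta_l <- eta_from_clustering(clustering, targets$p_l)
      des$eta_u <- eta_from_clustering(clustering, targets$p_u)
    }
    if (method == "hund") {
      des$D_l <- design_effect(m, des$rho_l)
      des$D_u <- design_effect(m, des$rho_u)
      des$n_eff_l <- effective_count(n, des$D_l)
      des$n_eff_u <- effective_count(n, des$D_u)
    }
  }
  structure(des, class = "cluster_design")
}

#' @export
print.cluster_design <- function(x, ...) {
  geom <- if (is.na(x$k)) sprintf("n = %d", x$n)
          else sprintf("n = %d (k = %d clusters x m = %d)", x$n, x$k, x$m)
  cat(sprintf("%s LQAS design: %s, decision rule d = %d\n",
              toupper(x$method), geom, x$d))
  cat(sprintf("  couplet (%.2f, %.2f), caps alpha = %.3g, beta = %.3g\n",
              x$targets$p_l, x$targets$p_u, x$targets$alpha, x$targets$beta))
  if (!is.null(x$clustering))
    cat(sprintf("  clustering at thresholds: rho_l = %.3f, rho_u = %.3f (sigma_l = %.3f, sigma_u = %.3f)\n",
                x$rho_l, x$rho_u, x$sigma_l, x$sigma_u))
  cat(sprintf("  achieved risks: alpha = %.3f, beta = %.3f (%s evaluation)\n",
              x$alpha, x$beta, x$evaluation))
  invisible(x)
}

#' @export
as.data.frame.cluster_design <- function(x, ...) {
  data.frame(method = x$method,
             p_l = x$targets$p_l, p_u = x$targets$p_u,
             n = x$n, d = x$d, k = x$k, m = x$m,
             alpha = x$alpha, beta = x$beta,
             rho_l = if (is.null(x$rho_l)) NA_real_ else x$rho_l,
             rho_u = if (is.null(x$rho_u)) NA_real_ else x$rho_u)
}
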