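#' Monte-Carlo estimate of achieved LQAS risks
#'
#' Estimates the provider and population risks of a given design by
#' simulation: independent draw sets of the survey total at `p_u` (for
#' `alpha`) and at `p_l` (for `beta`), with clustering resolved at each
#' threshold. For the quasi-binomial model draws and rule are compared
#' on the effective sample-size scale, matching the deterministic
#' evaluation in [model_risks()].
#'
#' @inheritParams model_risks
#' @param n_sims Number of draws per threshold (>= 100).
#' @param seed Optional seed, recorded in the result.
#' @return An object of class `"risk_estimate"`: a list with `alpha`,
#'   `beta`, their Monte-Carlo standard errors `mc_se_alpha` /
#'   `mc_se_beta` (`sqrt(r(1-r)/n_sims)`), `n_sims` and `seed`.
#' @examples
#' simulate_risks("pezzoli", k = 6, m = 10, d = 38,
#'                targets = design_targets(0.55, 0.70),
#'                clustering = clustering_spec(sigma = 0.1),
#'                n_sims = 2000, seed = 1)
#' @export
simulate_risks <- function(method, k, m, d, targets, clustering = NULL,
                           n_sims = 10000, seed = NULL,
                           scale = c("successes", "failures")) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  scale <- match.arg(scale)
  stopifnot(inherits(targets, "lqas_targets"))
  if (n_sims < 100) abort_usage("'n_sims' must be at least 100")
  n <- k * m
  if (d < 0 || d > n) abort_usage("'d' must lie in 0..n")
  if (!is.null(seed)) set.seed(seed)

  classify_low_frac <- function(p) {
    if (method == "hund" && !is.null(clustering) &&
        sigma_at(clustering, p) > 0) {
      ## compare on the effective scale, as in the deterministic evaluation
      D <- design_effect(m, rho_at(clustering, p))
      if (scale == "failures") {
        y <- stats::rbinom(n_sims, effective_count(n, D), 1 - p)
        return(mean(y > effective_count(d, D)))
      }
      x <- stats::rbinom(n_sims, effective_count(n, D), p)
      return(mean(x <= effective_count(d, D)))
    }
    d_succ <- if (scale == "failures") n - d - 1 else d
    x <- sample_total(method, k, m, p, clustering, n_draws = n_sims)
    mean(x <= d_succ)
  }

  alpha <- classify_low_frac(targets$p_u)
  beta <- 1 - classify_low_frac(targets$p_l)
  structure(list(alpha = alpha, beta = beta,
                 mc_se_alpha = sqrt(alpha * (1 - alpha) / n_sims),
                 mc_se_beta = sqrt(beta * (1 - beta) / n_sims),
                 n_sims = n_sims, seed = seed),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo risks (%d draws%s): alpha = %.3f (se %.4f), beta = %.3f (se %.4f)\n",
              x$n_sims, if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed),
              x$alpha, x$mc_se_alpha, x$beta, x$mc_se_beta))
  invisible(x)
}

#' Operating characteristic curve of a cluster LQAS design
#'
#' Computes the probability of classifying an area as acceptable,
#' \eqn{P(X > d)}, across a grid of true coverages. Clustering is
#' re-resolved at every grid point, so both fixed (`sigma` or `rho`)
#' and coverage-varying specifications are supported; with a fixed
#' specification the curve is non-decreasing in `p`.
#'
#' @inheritParams model_risks
#' @param p_grid Coverage grid inside (0, 1). When omitted, `targets`
#'   must be supplied and a default grid of 101 points on
#'   `[p_l/2, p_u + (1-p_u)/2]` (capped at 0.999) is used.
#' @param targets Optional [design_targets()], used for the default grid
#'   and recorded for plotting threshold reference lines.
#' @return An object of class `"lqas_oc"`: a data frame with columns
#'   `p` and `prob_accept`, carrying the design description as
#'   attributes.
#' @examples
#' oc <- oc_curve("hedt", k = 6, m = 10, d = 50,
#'                clustering = clustering_spec(rho = 0.1),
#'                targets = design_targets(0.75, 0.90))
#' head(oc)
#' @export
oc_curve <- function(method, k, m, d, clustering = NULL, p_grid = NULL,
                     targets = NULL, scale = c("successes", "failures")) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  scale <- match.arg(scale)
  n <- k * m
  if (d < 0 || d > n) abort_usage("'d' must lie in 0..n")
  if (is.null(p_grid)) {
    if (is.null(targets))
      abort_usage("supply 'p_grid' or 'targets' for the default grid")
    p_grid <- seq(0.5 * targets$p_l,
                  min(0.999, targets$p_u + (1 - targets$p_u) / 2),
                  length.out = 101)
  }
  if (any(p_grid <= 0 | p_grid >= 1))
    abort_usage("'p_grid' must lie strictly inside (0, 1)")

  accept_at <- function(p) {
    if (method == "hund" && !is.null(clustering) &&
        sigma_at(clustering, p) > 0) {
      D <- design_effect(m, rho_at(clustering, p))
      if (scale == "failures")
        return(stats::pbinom(effective_count(d, D), effective_count(n, D),
                             1 - p))
      return(stats::pbinom(effective_count(d, D), effective_count(n, D), p,
                           lower.tail = FALSE))
    }
    d_succ <- if (scale == "failures") n - d - 1 else d
    if (method == "hund")  # degenerate no-clustering limit
      return(stats::pbinom(d_succ, n, p, lower.tail = FALSE))
    1 - pmf_cdf(cluster_total_pmf(method, k, m, p, clustering), d_succ)
  }

  out <- data.frame(p = p_grid,
                    prob_accept = vapply(p_grid, accept_at, numeric(1)))
  structure(out, class = c("lqas_oc", "data.frame"),
            method = method, k = k, m = m, d = d, scale = scale,
            targets = targets, clustering = clustering)
}

#' Plot an operating characteristic curve
#'
#' Base-graphics plot of acceptance probability against true coverage,
#' with the design thresholds drawn as vertical reference lines when
#' known.
#'
#' @param x An `"lqas_oc"` object from [oc_curve()].
#' @param ... Passed on to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.lqas_oc <- function(x, ...) {
  plot(x$p, x$prob_accept, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "true coverage p", ylab = "P(classify acceptable)", ...)
  tg <- attr(x, "targets")
  if (!is.null(tg)) graphics::abline(v = c(tg$p_l, tg$p_u), lty = 3)
  invisible(x)
}

#' Side-by-side comparison of cluster LQAS designs
#'
#' Runs the minimal fixed-`m` design search for every combination of
#' threshold couplet, method, and clustering specification, and returns
#' a flat table with one row per design plus an SRS reference row per
#' couplet. Every row's achieved risks are re-checked against
#' [model_risks()] before the table is returned.
#'
#' @param targets_list A list of [design_targets()] objects (one per
#'   couplet).
#' @param m Within-cluster sample size used for all cluster designs.
#' @param clustering_list A list of [clustering_spec()] objects; each
#'   may carry a name used in the `clustering` column.
#' @param methods Character vector drawn from
#'   `c("pezzoli", "hedt", "hund")`.
#' @param k_max Cap passed to the searches.
#' @return A data frame with columns `p_l`, `p_u`, `method`,
#'   `clustering`, `n`, `d`, `k`, `m`, `alpha`, `beta`.
#' @examples
#' compare_designs(list(design_targets(0.75, 0.90)), m = 10,
#'                 clustering_list = list(clustering_spec(sigma = 0.1)),
#'                 methods = c("pezzoli", "hedt"))
#' @export
compare_designs <- function(targets_list, m,
                            clustering_list,
                            methods = c("pezzoli", "hedt", "hund"),
                            k_max = 2000) {
  if (length(targets_list) == 0L) abort_usage("'targets_list' must be non-empty")
  if (length(clustering_list) == 0L)
    abort_usage("'clustering_list' must be non-empty")
  if (length(methods) == 0L) {
    return(data.frame(p_l = numeric(0), p_u = numeric(0),
                      method = character(0), clustering = character(0),
                      n = integer(0), d = integer(0), k = integer(0),
                      m = integer(0), alpha = numeric(0), beta = numeric(0)))
  }
  methods <- match.arg(methods, c("pezzoli", "hedt", "hund"), several.ok = TRUE)
  labels <- names(clustering_list)
  if (is.null(labels)) labels <- rep("", length(clustering_list))
  rows <- list()
  for (tg in targets_list) {
    srs <- find_srs_design(tg)
    rows[[length(rows) + 1L]] <- data.frame(
      p_l = tg$p_l, p_u = tg$p_u, method = "srs", clustering = "",
      n = srs$n, d = srs$d, k = NA_integer_, m = NA_integer_,
      alpha = srs$alpha, beta = srs$beta)
    for (mt in methods) {
      for (ci in seq_along(clustering_list)) {
        cl <- clustering_list[[ci]]
        lab <- if (nzchar(labels[ci])) labels[ci] else describe_clustering(cl)
        des <- find_cluster_design(mt, tg, cl, m, k_max = k_max)
        audit <- model_risks(mt, des$k, des$m, des$d, tg, cl)
        if (abs(audit[["alpha"]] - des$alpha) > 1e-9 ||
            abs(audit[["beta"]] - des$beta) > 1e-9)
          stop("internal error: table row disagrees with model_risks()")
        rows[[length(rows) + 1L]] <- data.frame(
          p_l = tg$p_l, p_u = tg$p_u, method = mt, clustering = lab,
          n = des$n, d = des$d, k = des$k, m = des$m,
          alpha = des$alpha, beta = des$beta)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

describe_clustering <- function(cl) {
  switch(cl$mode,
    sigma_fixed = sprintf("sigma = %g", cl$sigma),
    rho_fixed = sprintf("rho = %g", cl$rho),
    function_of_p = "rho(p)")
}
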