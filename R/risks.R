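#' Misclassification risks of an LQAS rule under the binomial model
#'
#' Under simple random sampling the survey total is
#' \eqn{X \sim Binomial(n, p)} and the classification rule "accept if
#' \eqn{X > d}" has provider risk \eqn{\hat\alpha = P(X \le d \mid p_u)}
#' and population risk \eqn{\hat\beta = P(X > d \mid p_l)}, both
#' evaluated at the boundary of the grey region.
#'
#' @param n Total sample size.
#' @param d Decision rule on the success scale, `0 <= d <= n`.
#' @param p_l,p_u Coverage thresholds.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' binomial_risks(71, 44, 0.55, 0.70)  # (.091, .096)
#' @export
binomial_risks <- function(n, d, p_l, p_u) {
  stopifnot(n >= 1, n == round(n))
  if (d < 0 || d > n) abort_usage("'d' must lie in 0..n")
  n <- unname(n); d <- unname(d)
  c(alpha = stats::pbinom(d, n, p_u),
    beta = stats::pbinom(d, n, p_l, lower.tail = FALSE))
}

#' Exact distribution of the survey total under a cluster model
#'
#' Builds the exact pmf of \eqn{X = \sum_j X_j} for `k` clusters of `m`
#' subjects at coverage `p`, under the requested model with clustering
#' resolved at `p`. The quasi-binomial model has no distribution on the
#' original scale (it is defined through the effective sample size), so
#' it is not available here; use [model_risks()] for its risks.
#'
#' @param method One of `"srs"`, `"pezzoli"` (binomial-scaled) or
#'   `"hedt"` (beta-binomial).
#' @param k,m Cluster count and within-cluster sample size.
#' @param p Coverage at which to build the distribution.
#' @param clustering An [clustering_spec()] (ignored for `"srs"`).
#' @return A [total_pmf()] on `0..k*m`.
#' @examples
#' cluster_total_pmf("hedt", k = 6, m = 10, p = 0.7,
#'                   clustering = clustering_spec(rho = 0.1))
#' @export
cluster_total_pmf <- function(method, k, m, p, clustering = NULL) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt"))
  stopifnot(k >= 1, m >= 1)
  if (method == "srs") return(total_pmf(stats::dbinom(0:(k * m), k * m, p)))
  if (is.null(clustering)) abort_usage("'clustering' is required for cluster models")
  if (sigma_at(clustering, p) == 0)
    return(total_pmf(stats::dbinom(0:(k * m), k * m, p)))
  cl <- switch(method,
    pezzoli = binomial_scaled_pmf(m, p, eta_from_clustering(clustering, p)),
    hedt = betabinomial_pmf(m, p, rho_at(clustering, p)))
  convolve_iid(cl, k)
}

#' Achieved risks of a cluster LQAS design
#'
#' Evaluates the provider and population risks of the rule `d` for a
#' `k x m` design under one of the four models. Clustering is resolved
#' separately at each threshold: with `sigma` fixed the implied `rho`
#' (and mixing index `eta`) differ between `p_l` and `p_u`, and vice
#' versa. The binomial-scaled and beta-binomial risks come from the
#' exact convolved pmf; the quasi-binomial ("hund") risks from the
#' binomial distribution on the effective-sample-size scale, with
#' nearest-integer rounding of `n/D` and `d/D`.
#'
#' Some survey traditions state the rule as a maximum number of
#' *failures* (e.g. malnutrition cases) rather than successes. With
#' `scale = "failures"`, `d` is interpreted as that case-count rule:
#' the area is accepted when failures are at most `d`, equivalent to
#' successes exceeding `n - d - 1`. The conversion is exact for the
#' distribution-based models; for the quasi-binomial model the
#' effective-scale rounding is applied on the scale on which the rule
#' is expressed, which matters because rounding does not commute with
#' the conversion.
#'
#' @param method `"srs"`, `"pezzoli"`, `"hedt"` or `"hund"`.
#' @param k,m Cluster count and within-cluster sample size (`n = k*m`).
#' @param d Decision rule (see `scale`).
#' @param targets An [design_targets()] object.
#' @param clustering An [clustering_spec()] object (ignored for `"srs"`).
#' @param scale `"successes"` (default) or `"failures"`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' tg <- design_targets(0.75, 0.90)
#' model_risks("hund", k = 8, m = 10, d = 66, targets = tg,
#'             clustering = clustering_spec(rho = 0.11))   # (.100, .096)
#' model_risks("hedt", k = 11, m = 10, d = 68,
#'             targets = design_targets(0.55, 0.70),
#'             clustering = clustering_spec(rho = 0.04))
#' @export
model_risks <- function(method, k, m, d, targets, clustering = NULL,
                        scale = c("successes", "failures")) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  scale <- match.arg(scale)
  stopifnot(inherits(targets, "lqas_targets"), k >= 1, m >= 1)
  k <- unname(k); m <- unname(m); d <- unname(d)
  n <- k * m
  if (d < 0 || d > n) abort_usage("'d' must lie in 0..n")

  if (method == "hund") {
    if (is.null(clustering)) abort_usage("'clustering' is required for 'hund'")
    D_l <- design_effect(m, rho_at(clustering, targets$p_l))
    D_u <- design_effect(m, rho_at(clustering, targets$p_u))
    if (scale == "failures") {
      ## effective case-count threshold; failure probability 1 - p
      alpha <- stats::pbinom(effective_count(d, D_u), effective_count(n, D_u),
                             1 - targets$p_u, lower.tail = FALSE)
      beta <- stats::pbinom(effective_count(d, D_l), effective_count(n, D_l),
                            1 - targets$p_l)
    } else {
      alpha <- stats::pbinom(effective_count(d, D_u), effective_count(n, D_u),
                             targets$p_u)
      beta <- stats::pbinom(effective_count(d, D_l), effective_count(n, D_l),
                            targets$p_l, lower.tail = FALSE)
    }
    return(c(alpha = alpha, beta = beta))
  }

  d_succ <- if (scale == "failures") n - d - 1 else d
  if (d_succ < 0 || d_succ > n) abort_usage("converted rule falls outside 0..n")
  if (method == "srs") return(binomial_risks(n, d_succ, targets$p_l, targets$p_u))
  pmf_l <- cluster_total_pmf(method, k, m, targets$p_l, clustering)
  pmf_u <- cluster_total_pmf(method, k, m, targets$p_u, clustering)
  c(alpha = pmf_cdf(pmf_u, d_succ), beta = 1 - pmf_cdf(pmf_l, d_succ))
}

#' Convert a failure-count rule to the success scale
#'
#' An area is accepted when the number of failures is at most `d_fail`,
#' i.e. when successes exceed `n - d_fail - 1`.
#'
#' @param n Total sample size.
#' @param d_fail Maximum acceptable failure count.
#' @return The equivalent success-scale rule `n - d_fail - 1`.
#' @examples
#' failure_to_success_rule(198, 13)  # 184
#' @export
failure_to_success_rule <- function(n, d_fail) {
  if (d_fail < 0 || d_fail > n - 1)
    abort_usage("'d_fail' must lie in 0..(n-1)")
  n - d_fail - 1
}
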