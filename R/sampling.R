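#' Simulate survey totals from a cluster LQAS model
#'
#' Draws survey totals \eqn{X = \sum_j X_j} under the requested model at
#' coverage `p`. The beta-binomial model draws latent cluster coverages
#' \eqn{p_j} from a beta distribution and the binomial-scaled model from
#' a scaled binomial lattice, then cluster counts
#' \eqn{X_j \sim Binomial(m, p_j)}. The quasi-binomial model has no
#' cluster-level representation: a count is drawn on the effective
#' sample-size scale and rescaled by the design effect, consistent with
#' the deterministic effective-scale risk evaluation in [model_risks()].
#' Randomness comes from R's global stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param method `"srs"`, `"pezzoli"`, `"hedt"` or `"hund"`.
#' @param k,m Cluster count and within-cluster sample size.
#' @param p True coverage at which to simulate.
#' @param clustering An [clustering_spec()] (ignored for `"srs"`).
#' @param n_draws Number of independent survey totals to draw.
#' @param latent If `TRUE`, also return the per-cluster counts and (for
#'   the two-stage models) the latent cluster coverages.
#' @return A numeric vector of `n_draws` totals, or, when
#'   `latent = TRUE`, a list with `totals`, `counts` (a `k x n_draws`
#'   matrix) and `coverages`.
#' @examples
#' set.seed(1)
#' sample_total("hedt", k = 6, m = 10, p = 0.7,
#'              clustering = clustering_spec(rho = 0.1), n_draws = 5)
#' @export
sample_total <- function(method, k, m, p, clustering = NULL, n_draws = 1,
                         latent = FALSE) {
  method <- match.arg(method, c("srs", "pezzoli", "hedt", "hund"))
  stopifnot(k >= 1, m >= 1, n_draws >= 1)
  if (p <= 0 || p >= 1) abort_usage("'p' must lie strictly in (0, 1)")
  n <- k * m
  if (method != "srs") {
    if (is.null(clustering)) abort_usage("'clustering' is required for cluster models")
    if (sigma_at(clustering, p) == 0) method <- "srs"  # no-clustering limit
  }

  if (method == "srs") {
    totals <- stats::rbinom(n_draws, n, p)
    if (!latent) return(totals)
    ## split each total into per-cluster binomial counts for completeness
    counts <- matrix(stats::rbinom(k * n_draws, m, p), nrow = k)
    return(list(totals = colSums(counts), counts = counts, coverages = NULL))
  }
  if (method == "hund") {
    D <- design_effect(m, rho_at(clustering, p))
    xs <- stats::rbinom(n_draws, effective_count(n, D), p)
    totals <- pmin(n, round_half_up(D * xs))
    if (latent) return(list(totals = totals, counts = NULL, coverages = NULL))
    return(totals)
  }
  pj <- switch(method,
    hedt = {
      rho <- rho_at(clustering, p)
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      stats::rbeta(k * n_draws, a, b)
    },
    pezzoli = {
      eta <- eta_from_clustering(clustering, p)
      stats::rbinom(k * n_draws, eta, p) / eta
    })
  counts <- matrix(stats::rbinom(k * n_draws, m, pj), nrow = k)
  totals <- colSums(counts)
  if (latent)
    list(totals = totals, counts = counts,
         coverages = matrix(pj, nrow = k))
  else totals
}
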