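#' Probability mass function on the survey-total scale
#'
#' Light container for the distribution of a count on support
#' `0..n`. The constructor checks non-negativity and renormalizes away
#' floating-point drift up to `1e-6` (larger deviations are an error).
#'
#' @param probs Numeric vector of `n + 1` masses for the values `0..n`.
#' @return An object of class `"total_pmf"`: a list with elements `n`
#'   and `probs`.
#' @examples
#' total_pmf(dbinom(0:10, 10, 0.3))
#' @export
total_pmf <- function(probs) {
  stopifnot(is.numeric(probs), length(probs) >= 1L)
  if (any(probs < -1e-12)) abort_usage("pmf masses must be non-negative")
  probs <- pmax(probs, 0)
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-6)
    abort_usage(sprintf("pmf masses sum to %.8f, not 1", tot))
  if (abs(tot - 1) > 1e-12) probs <- probs / tot
  structure(list(n = length(probs) - 1L, probs = probs), class = "total_pmf")
}

#' @export
print.total_pmf <- function(x, ...) {
  cat(sprintf("Probability mass function on 0..%d (mean %.4f, sd %.4f)\n",
              x$n, pmf_mean(x), sqrt(pmf_variance(x))))
  invisible(x)
}

#' @export
as.data.frame.total_pmf <- function(x, ...) {
  data.frame(x = 0:x$n, mass = x$probs)
}

#' Moments and tail probabilities of a total pmf
#'
#' @param pmf A [total_pmf()] object (or bare vector of masses).
#' @param q Quantile at which to evaluate the cumulative distribution.
#' @return A numeric scalar.
#' @export
pmf_mean <- function(pmf) {
  p <- pmf_probs(pmf)
  sum((seq_along(p) - 1) * p)
}

#' @rdname pmf_mean
#' @export
pmf_variance <- function(pmf) {
  p <- pmf_probs(pmf)
  x <- seq_along(p) - 1
  sum(x^2 * p) - pmf_mean(pmf)^2
}

#' @rdname pmf_mean
#' @export
pmf_cdf <- function(pmf, q) {
  p <- pmf_probs(pmf)
  n <- length(p) - 1L
  vapply(q, function(qi) {
    if (qi < 0) 0 else if (qi >= n) 1 else sum(p[1:(floor(qi) + 1L)])
  }, numeric(1))
}

pmf_probs <- function(pmf) {
  if (inherits(pmf, "total_pmf")) pmf$probs else as.numeric(pmf)
}

#' Beta-binomial cluster count distribution
#'
#' Distribution of the number of successes \eqn{X_j} among `m` subjects
#' in one cluster when the cluster coverage is beta-distributed with
#' mean `p` and intraclass correlation `rho` (beta shapes
#' \eqn{a = p(1-\rho)/\rho}, \eqn{b = (1-p)(1-\rho)/\rho}). The mean is
#' \eqn{mp} and the variance \eqn{mp(1-p)\{1 + (m-1)\rho\}}. `rho = 0`
#' reduces to the plain binomial; `rho = 1` puts all mass on 0 and `m`.
#'
#' @param m Within-cluster sample size.
#' @param p Mean coverage in (0, 1).
#' @param rho Intraclass correlation in \eqn{[0, 1]}.
#' @return A [total_pmf()] on `0..m`.
#' @examples
#' betabinomial_pmf(10, 0.7, 0.05)
#' @export
betabinomial_pmf <- function(m, p, rho) {
  stopifnot(m >= 1, m == round(m))
  if (p <= 0 || p >= 1) abort_usage("'p' must lie strictly in (0, 1)")
  if (rho < 0 || rho > 1) abort_usage("'rho' must lie in [0, 1]")
  if (rho == 0) return(total_pmf(stats::dbinom(0:m, m, p)))
  if (rho == 1) {  # degenerate: whole cluster all-failure or all-success
    probs <- numeric(m + 1); probs[1] <- 1 - p; probs[m + 1] <- p
    return(total_pmf(probs))
  }
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  x <- 0:m
  total_pmf(exp(lchoose(m, x) + lbeta(x + a, m - x + b) - lbeta(a, b)))
}

#' Binomial-scaled cluster count distribution
#'
#' Distribution of the cluster count \eqn{X_j} when the cluster coverage
#' is drawn on a lattice, \eqn{p_j = B/\eta} with
#' \eqn{B \sim Binomial(\eta, p)}, and \eqn{X_j \mid p_j \sim
#' Binomial(m, p_j)}. The coverage spread is
#' \eqn{sd(p_j) = \sqrt{p(1-p)/\eta}}. Because \eqn{p_j} has only
#' \eqn{\eta + 1} support points the marginal pmf is a finite mixture and
#' is computed exactly, so no simulation is needed to evaluate designs
#' under this model.
#'
#' @param m Within-cluster sample size.
#' @param p Mean coverage in (0, 1).
#' @param eta Integer mixing index \eqn{\ge 1}; see
#'   [eta_from_clustering()].
#' @return A [total_pmf()] on `0..m`.
#' @examples
#' binomial_scaled_pmf(10, 0.7, 21)
#' @export
binomial_scaled_pmf <- function(m, p, eta) {
  stopifnot(m >= 1, m == round(m))
  if (p <= 0 || p >= 1) abort_usage("'p' must lie strictly in (0, 1)")
  if (eta < 1 || eta != round(eta))
    abort_usage("'eta' must be a positive integer")
  w <- stats::dbinom(0:eta, eta, p)
  comp <- vapply(0:eta, function(j) stats::dbinom(0:m, m, j / eta),
                 numeric(m + 1))
  total_pmf(as.vector(comp %*% w))
}

#' Exact distribution of a sum of iid cluster counts
#'
#' k-fold convolution of a single-cluster pmf, giving the exact
#' distribution of the survey total \eqn{X = \sum_j X_j} over `k`
#' independent clusters. Uses iterated direct convolution (supports here
#' are far too small for FFT to matter) and renormalizes accumulated
#' floating-point drift.
#'
#' @param cluster_pmf A [total_pmf()] (or mass vector) on `0..m`.
#' @param k Number of clusters (\eqn{\ge 1}).
#' @return A [total_pmf()] on `0..k*m`.
#' @examples
#' convolve_iid(betabinomial_pmf(10, 0.7, 0.05), 6)
#' @export
convolve_iid <- function(cluster_pmf, k) {
  if (k < 1 || k != round(k)) abort_usage("'k' must be a positive integer")
  base <- pmf_probs(cluster_pmf)
  out <- 1
  for (i in seq_len(k)) out <- conv_pair(out, base)
  total_pmf(out)
}

conv_pair <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    idx <- j:(j + length(a) - 1L)
    out[idx] <- out[idx] + b[j] * a
  }
  out
}
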