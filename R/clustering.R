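#' Convert between the sigma and rho clustering parameterizations
#'
#' In a two-stage cluster sample the cluster-level coverages \eqn{p_j}
#' scatter around the overall coverage `p` with standard deviation
#' \eqn{\sigma}. The intraclass correlation is
#' \deqn{\rho = \sigma^2 / \{p(1-p)\},}
#' so the two clustering parameterizations are interchangeable once the
#' coverage at which they are evaluated is fixed. Holding \eqn{\sigma}
#' fixed implies more intraclass correlation as `p` approaches 0 or 1;
#' holding \eqn{\rho} fixed implies less spread in \eqn{p_j} away from
#' `p = 0.5`.
#'
#' @param sigma Standard deviation of the true cluster coverages
#'   (a proportion, \eqn{\ge 0}).
#' @param rho Intraclass correlation in \eqn{[0, 1]}.
#' @param p Coverage at which the conversion is evaluated, in (0, 1).
#'
#' @return `rho_from_sigma()` returns the intraclass correlation;
#'   `sigma_from_rho()` returns the cluster-coverage standard deviation.
#'
#' @examples
#' rho_from_sigma(0.1, 0.9)   # 0.111
#' sigma_from_rho(0.1, 0.55)  # 0.157
#' @export
rho_from_sigma <- function(sigma, p) {
  stopifnot(is.numeric(sigma), is.numeric(p))
  if (any(p <= 0 | p >= 1)) abort_usage("'p' must lie strictly in (0, 1)")
  if (any(sigma < 0)) abort_usage("'sigma' must be non-negative")
  v <- p * (1 - p)
  if (any(sigma^2 > v + 1e-12))
    abort_clustering(sprintf(
      "sigma = %g exceeds the maximum attainable spread at p = %g (implied rho > 1)",
      max(sigma), p[which.max(sigma^2 - v)][1]))
  pmin(sigma^2 / v, 1)
}

#' @rdname rho_from_sigma
#' @export
sigma_from_rho <- function(rho, p) {
  stopifnot(is.numeric(rho), is.numeric(p))
  if (any(p <= 0 | p >= 1)) abort_usage("'p' must lie strictly in (0, 1)")
  if (any(rho < 0 | rho > 1)) abort_usage("'rho' must lie in [0, 1]")
  sqrt(rho * p * (1 - p))
}

#' Design effect and effective counts for two-stage cluster samples
#'
#' The design effect \eqn{D = 1 + (m - 1)\rho} is the factor by which
#' cluster sampling inflates the variance of a coverage estimate relative
#' to simple random sampling with the same total size. Dividing a count
#' (sample size or decision rule) by `D` and rounding to the nearest
#' integer puts it on the effective, independent-observation scale used
#' by the quasi-binomial evaluation. Halves round away from zero.
#'
#' @param m Within-cluster sample size (\eqn{\ge 1}).
#' @param rho Intraclass correlation in \eqn{[0, 1]}.
#' @param x Count (sample size or decision rule) on the original scale.
#' @param D Design effect (\eqn{\ge 1}).
#'
#' @return `design_effect()` returns \eqn{D \ge 1}; `effective_count()`
#'   returns the nearest integer to `x / D`.
#'
#' @examples
#' design_effect(10, 0.11)      # 1.99
#' effective_count(80, 1.99)    # 40
#' @export
design_effect <- function(m, rho) {
  stopifnot(is.numeric(m), is.numeric(rho))
  if (any(m < 1)) abort_usage("'m' must be at least 1")
  if (any(rho < 0 | rho > 1)) abort_usage("'rho' must lie in [0, 1]")
  1 + (m - 1) * rho
}

#' @rdname design_effect
#' @export
effective_count <- function(x, D) {
  stopifnot(is.numeric(x), is.numeric(D))
  if (any(x < 0)) abort_usage("'x' must be non-negative")
  if (any(D < 1)) abort_usage("design effect 'D' must be at least 1")
  round_half_up(x / D)
}

#' Specify the clustering model for a cluster LQAS design
#'
#' Clustering can be supplied in one of three ways: a fixed
#' cluster-coverage standard deviation `sigma` (the binomial-scaled
#' tradition), a fixed intraclass correlation `rho` (the beta-binomial /
#' design-effect tradition), or a coverage-dependent function giving
#' \eqn{\rho(p)}. The coverage-dependent form accepts either a function
#' or a two-column data frame of `(p, rho)` pairs, which is interpolated
#' linearly and extrapolated flat beyond its range; a smoother fitted to
#' historical estimates can populate such a grid.
#'
#' @param sigma Fixed standard deviation of cluster coverages, or `NULL`.
#' @param rho Fixed intraclass correlation, or `NULL`.
#' @param rho_of_p A function of `p` returning \eqn{\rho}, or a data
#'   frame with columns `p` and `rho`, or `NULL`. Exactly one of the
#'   three arguments must be supplied.
#'
#' @return An object of class `"lqas_clustering"` with a `mode` field
#'   (`"sigma_fixed"`, `"rho_fixed"` or `"function_of_p"`).
#'
#' @examples
#' clustering_spec(sigma = 0.1)
#' clustering_spec(rho = 0.1)
#' clustering_spec(rho_of_p = data.frame(p = c(0.5, 0.9), rho = c(0.12, 0.04)))
#' @export
clustering_spec <- function(sigma = NULL, rho = NULL, rho_of_p = NULL) {
  supplied <- c(sigma = !is.null(sigma), rho = !is.null(rho),
                rho_of_p = !is.null(rho_of_p))
  if (sum(supplied) != 1L)
    abort_usage("supply exactly one of 'sigma', 'rho' or 'rho_of_p'")
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
      abort_usage("'sigma' must be a single non-negative number")
    out <- list(mode = "sigma_fixed", sigma = sigma)
  } else if (!is.null(rho)) {
    if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
      abort_usage("'rho' must be a single number in [0, 1)")
    out <- list(mode = "rho_fixed", rho = rho)
  } else {
    if (is.data.frame(rho_of_p)) {
      if (!all(c("p", "rho") %in% names(rho_of_p)) || nrow(rho_of_p) < 1L)
        abort_usage("'rho_of_p' data frame needs columns 'p' and 'rho'")
      grid <- rho_of_p[order(rho_of_p$p), c("p", "rho")]
      fn <- if (nrow(grid) == 1L) {
        local({ val <- grid$rho[1]; function(p) rep(val, length(p)) })
      } else {
        stats::approxfun(grid$p, grid$rho, rule = 2)
      }
      out <- list(mode = "function_of_p", rho_of_p = fn, grid = grid)
    } else if (is.function(rho_of_p)) {
      out <- list(mode = "function_of_p", rho_of_p = rho_of_p)
    } else {
      abort_usage("'rho_of_p' must be a function or a data frame")
    }
  }
  structure(out, class = "lqas_clustering")
}

#' @export
print.lqas_clustering <- function(x, ...) {
  switch(x$mode,
    sigma_fixed = cat(sprintf("Clustering: sigma fixed at %g\n", x$sigma)),
    rho_fixed = cat(sprintf("Clustering: rho fixed at %g\n", x$rho)),
    function_of_p = cat("Clustering: rho varying with coverage p\n"))
  invisible(x)
}

#' Resolve clustering at a given coverage
#'
#' Evaluates a clustering specification at coverage `p`, returning the
#' implied intraclass correlation or cluster-coverage standard deviation
#' at that point (they are linked through `rho = sigma^2 / (p(1-p))`).
#'
#' @param spec An [clustering_spec()] object (a bare number is accepted
#'   by `rho_at()`/`sigma_at()` and treated as a fixed `rho`/`sigma`).
#' @param p Coverage in (0, 1) at which to resolve.
#' @return A numeric value of the same length as `p`.
#' @examples
#' rho_at(clustering_spec(sigma = 0.1), 0.9)  # 0.111
#' sigma_at(clustering_spec(rho = 0.1), 0.55) # 0.157
#' @export
rho_at <- function(spec, p) {
  if (is.numeric(spec)) spec <- clustering_spec(rho = spec)
  stopifnot(inherits(spec, "lqas_clustering"))
  if (any(p <= 0 | p >= 1)) abort_usage("'p' must lie strictly in (0, 1)")
  switch(spec$mode,
    sigma_fixed = rho_from_sigma(spec$sigma, p),
    rho_fixed = rep(spec$rho, length(p)),
    function_of_p = {
      r <- spec$rho_of_p(p)
      if (any(!is.finite(r) | r < 0 | r >= 1))
        abort_clustering(sprintf(
          "clustering function returned an invalid rho (%s) at p = %s",
          paste(signif(r[!is.finite(r) | r < 0 | r >= 1], 4), collapse = ", "),
          paste(signif(p[!is.finite(r) | r < 0 | r >= 1], 4), collapse = ", ")))
      r
    })
}

#' @rdname rho_at
#' @export
sigma_at <- function(spec, p) {
  if (is.numeric(spec)) spec <- clustering_spec(sigma = spec)
  stopifnot(inherits(spec, "lqas_clustering"))
  if (spec$mode == "sigma_fixed") {
    ## validate that the fixed sigma is attainable at this p
    rho_from_sigma(spec$sigma, p)
    rep(spec$sigma, length(p))
  } else {
    sigma_from_rho(rho_at(spec, p), p)
  }
}

#' Mixing index of the binomial-scaled cluster model
#'
#' The binomial-scaled model draws the cluster coverage as
#' \eqn{p_j = B/\eta} with \eqn{B \sim Binomial(\eta, p)}, so
#' \eqn{sd(p_j) = \sqrt{p(1-p)/\eta}}. The mixing index is chosen so
#' that the implied spread matches the requested clustering,
#' \eqn{\eta = p(1-p)/\sigma^2 = 1/\rho}, rounded to the nearest
#' integer (at least 1).
#'
#' @inheritParams rho_at
#' @return Integer mixing index \eqn{\eta \ge 1}.
#' @examples
#' eta_from_clustering(clustering_spec(sigma = 0.1), 0.9)  # 9
#' eta_from_clustering(clustering_spec(sigma = 0.1), 0.7)  # 21
#' @export
eta_from_clustering <- function(spec, p) {
  if (is.numeric(spec)) spec <- clustering_spec(sigma = spec)
  rho <- rho_at(spec, p)
  if (any(rho == 0))
    abort_clustering(
      "clustering is degenerate (sigma = 0); use the plain binomial model")
  as.integer(pmax(1, round_half_up(1 / rho)))
}
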