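#' LQAS design targets
#'
#' Bundles the coverage threshold couplet and the misclassification risk
#' caps that define an LQAS design. An area with true coverage at or above
#' `p_u` should rarely be classified "low" (probability at most `alpha`,
#' the service-provider risk), and an area with coverage at or below `p_l`
#' should rarely be classified "high" (probability at most `beta`, the
#' population risk). Risks are unconstrained in the grey region between
#' the two thresholds.
#'
#' @param p_l Lower coverage threshold, a proportion strictly between 0
#'   and 1.
#' @param p_u Upper coverage threshold, strictly between `p_l` and 1.
#' @param alpha Cap on the provider risk \eqn{P(X \le d \mid p = p_u)}.
#' @param beta Cap on the population risk \eqn{P(X > d \mid p = p_l)}.
#'
#' @return An object of class `"lqas_targets"`: a list with elements
#'   `p_l`, `p_u`, `alpha` and `beta`.
#'
#' @examples
#' design_targets(0.75, 0.90)
#' design_targets(0.55, 0.70, alpha = 0.05, beta = 0.10)
#' @export
design_targets <- function(p_l, p_u, alpha = 0.1, beta = 0.1) {
  for (v in c("p_l", "p_u", "alpha", "beta")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      abort_usage(sprintf("'%s' must be a single numeric value", v))
  }
  if (p_l <= 0 || p_u >= 1 || p_l >= p_u)
    abort_usage("thresholds must satisfy 0 < p_l < p_u < 1")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    abort_usage("risk caps 'alpha' and 'beta' must lie in (0, 1)")
  structure(list(p_l = p_l, p_u = p_u, alpha = alpha, beta = beta),
            class = "lqas_targets")
}

#' @export
print.lqas_targets <- function(x, ...) {
  cat(sprintf("LQAS design targets: p_l = %g, p_u = %g, alpha = %g, beta = %g\n",
              x$p_l, x$p_u, x$alpha, x$beta))
  invisible(x)
}

## condition helpers -- classed errors so the CLI can map them to exit codes
abort_usage <- function(msg) {
  stop(errorCondition(msg, class = c("clqas_usage_error", "clqas_error")))
}
abort_clustering <- function(msg) {
  stop(errorCondition(msg, class = c("clqas_invalid_clustering", "clqas_error")))
}
abort_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("clqas_infeasible", "clqas_error")))
}

## nearest-integer rounding with halves away from zero, the convention used
## for the mixing index eta and for effective counts x/D
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
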