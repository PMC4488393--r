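#' Estimate between-cluster variance from survey summary statistics
#'
#' Published cluster-survey reports typically give the estimated coverage
#' \eqn{\hat p} and the standard deviation `s` of the *estimated*
#' cluster-level coverages \eqn{\hat p_j = X_j / m}. Because each
#' \eqn{\hat p_j} carries binomial estimation noise, `s` overestimates
#' the spread \eqn{\sigma} of the true cluster coverages. Under the
#' two-stage model (\eqn{p_j} with mean \eqn{p} and variance
#' \eqn{\sigma^2}; \eqn{X_j \mid p_j \sim Binomial(m, p_j)}) a
#' moment-based correction gives
#' \deqn{\hat\sigma^2 = \frac{m s^2 - \hat p(1 - \hat p)}{m - 1},}
#' truncated at zero when the within-cluster noise exceeds the observed
#' between-cluster spread. The estimator is unbiased as \eqn{m} or the
#' number of clusters grows.
#'
#' @param p_hat Estimated overall coverage(s), in \eqn{[0, 1]}.
#' @param s Standard deviation(s) of the estimated cluster coverages.
#'   If a report gives a standard error `se` of \eqn{\hat p} instead,
#'   convert with `s = se * sqrt(k)`.
#' @param m Within-cluster sample size(s), at least 2.
#'
#' @return A data frame with one row per input and columns
#' \describe{
#'   \item{sigma2}{the truncated variance estimate \eqn{\hat\sigma^2};}
#'   \item{sigma}{its square root;}
#'   \item{rho}{the implied intraclass correlation
#'     \eqn{\hat\sigma^2/\{\hat p(1-\hat p)\}} (`NA` when `p_hat` is 0 or 1);}
#'   \item{truncated}{logical, `TRUE` when the raw estimate was negative
#'     (or exactly zero at the boundary) and was truncated, so "no
#'     clustering observed" can be told apart from a genuinely zero
#'     estimate;}
#'   \item{sigma2_raw}{the untruncated moment estimate, which can be
#'     negative. Its average is the unbiased quantity, so use it when
#'     pooling estimates across many areas; truncation biases the
#'     pooled mean upward, noticeably so when `sigma^2` is small
#'     relative to the within-cluster noise \eqn{p(1-p)/m}.}
#' }
#'
#' @examples
#' estimate_sigma2(p_hat = 0.9, s = 0.2, m = 6)   # sigma2 = 0.03
#' estimate_sigma2(p_hat = 0.5, s = sqrt(0.025), m = 10)  # truncated to 0
#' @export
estimate_sigma2 <- function(p_hat, s, m) {
  stopifnot(is.numeric(p_hat), is.numeric(s), is.numeric(m))
  nn <- max(length(p_hat), length(s), length(m))
  p_hat <- rep_len(p_hat, nn); s <- rep_len(s, nn); m <- rep_len(m, nn)
  if (any(m < 2)) abort_usage("'m' must be at least 2 for the variance estimator")
  if (any(p_hat < 0 | p_hat > 1)) abort_usage("'p_hat' must lie in [0, 1]")
  if (any(s < 0)) abort_usage("'s' must be non-negative")
  raw <- (m * s^2 - p_hat * (1 - p_hat)) / (m - 1)
  sigma2 <- pmax(0, raw)
  rho <- ifelse(p_hat > 0 & p_hat < 1, sigma2 / (p_hat * (1 - p_hat)), NA_real_)
  data.frame(sigma2 = sigma2, sigma = sqrt(sigma2), rho = rho,
             truncated = raw <= 0, sigma2_raw = raw)
}

#' Assemble one area's survey summary record
#'
#' Builds a one-row data frame in the survey-summary schema used by
#' [read_survey_summaries()] and [estimate_clustering()]. Exactly one of
#' `s` (standard deviation of estimated cluster coverages) or `se`
#' (standard error of the overall coverage estimate) must be given; a
#' standard error is converted via `s = se * sqrt(k)`.
#'
#' @param area_id Label for the supervision area.
#' @param p_hat Estimated coverage in \eqn{[0, 1]}.
#' @param k Number of clusters sampled (\eqn{\ge 2}).
#' @param m Within-cluster sample size (\eqn{\ge 1}).
#' @param s,se Spread summaries; supply exactly one.
#' @param rho_hat Optional reported intraclass correlation estimate.
#' @return A one-row data frame with columns `area_id`, `p_hat`, `s`,
#'   `se`, `k`, `m`, `rho_hat`.
#' @examples
#' survey_summary("A01", p_hat = 0.9, se = 0.05, k = 16, m = 6)
#' @export
survey_summary <- function(area_id, p_hat, k, m, s = NULL, se = NULL,
                           rho_hat = NA_real_) {
  if (is.null(s) == is.null(se))
    abort_usage("supply exactly one of 's' or 'se'")
  if (!is.numeric(p_hat) || p_hat < 0 || p_hat > 1)
    abort_usage("'p_hat' must lie in [0, 1]")
  if (k < 2) abort_usage("'k' must be at least 2")
  if (m < 1) abort_usage("'m' must be at least 1")
  if ((if (is.null(s)) se else s) < 0)
    abort_usage("'s' (or 'se') must be non-negative")
  data.frame(area_id = as.character(area_id), p_hat = p_hat,
             s = if (is.null(s)) NA_real_ else s,
             se = if (is.null(se)) NA_real_ else se, k = as.integer(k),
             m = as.integer(m), rho_hat = rho_hat)
}

#' Per-area clustering estimates from a survey-summary table
#'
#' Applies the between-cluster variance estimator to each row of a
#' survey-summary table (as returned by [read_survey_summaries()],
#' [survey_summary()] or [simulate_survey_summaries()]) and appends the
#' estimates.
#'
#' @param summaries Data frame with columns `area_id`, `p_hat`, `k`,
#'   `m` and at least one of `s` / `se` per row.
#' @return The input with columns `sigma2_hat`, `sigma_hat`,
#'   `rho_hat_est` and `truncated` appended.
#' @seealso [estimate_sigma2()] for the estimator itself.
#' @export
estimate_clustering <- function(summaries) {
  summaries <- validate_survey_summaries(summaries)
  est <- estimate_sigma2(summaries$p_hat, summaries$s, summaries$m)
  summaries$sigma2_hat <- est$sigma2
  summaries$sigma_hat <- est$sigma
  summaries$rho_hat_est <- est$rho
  summaries$truncated <- est$truncated
  summaries$sigma2_raw <- est$sigma2_raw
  summaries
}

## Schema check shared by the reader and the estimator; fills s from se
## where needed and drops malformed rows with a line-numbered warning.
validate_survey_summaries <- function(df, source = "survey summaries") {
  required <- c("area_id", "p_hat", "k", "m")
  if (!all(required %in% names(df)))
    abort_usage(sprintf("%s must have columns %s and one of 's'/'se'",
                        source, paste(required, collapse = ", ")))
  if (!"s" %in% names(df)) df$s <- NA_real_
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"rho_hat" %in% names(df)) df$rho_hat <- NA_real_
  has_s <- !is.na(df$s)
  has_se <- !is.na(df$se)
  df$s[!has_s & has_se] <- df$se[!has_s & has_se] * sqrt(df$k[!has_s & has_se])
  ## exactly one spread field per row; both are tolerated only when
  ## consistent (s = se * sqrt(k)), as in a previously validated frame
  both_ok <- has_s & has_se &
    abs(df$s - df$se * sqrt(df$k)) < 1e-8 * pmax(1, df$s)
  bad <- ((has_s == has_se) & !both_ok) |          # neither, or conflicting
    is.na(df$p_hat) | df$p_hat < 0 | df$p_hat > 1 |
    is.na(df$k) | df$k < 2 | is.na(df$m) | df$m < 1 |
    (!is.na(df$s) & df$s < 0)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sprintf("%s: skipping %d malformed row(s) at line(s) %s",
                    source, sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort_usage(sprintf("%s: no valid rows", source))
  df[c("area_id", "p_hat", "s", "se", "k", "m", "rho_hat")]
}
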