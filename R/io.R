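#' Read a survey-summary table from CSV
#'
#' Reads published per-area summaries in the package's survey-summary
#' schema: a header row with columns `area_id, p_hat, s, se, k, m,
#' rho_hat` (UTF-8, `.` decimal separator). Exactly one of `s` / `se`
#' must be non-empty per row; a standard error is converted to the
#' cluster-coverage standard deviation via `s = se * sqrt(k)`.
#' Malformed rows are skipped with a warning naming their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame with columns `area_id`, `p_hat`, `s`,
#'   `se`, `k`, `m`, `rho_hat`.
#' @seealso [estimate_clustering()], [simulate_survey_summaries()]
#' @export
read_survey_summaries <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(area_id = "character"))
  validate_survey_summaries(df, source = path)
}

#' Simulate per-area survey summaries from a two-stage cluster model
#'
#' Generates the summary statistics that cluster-survey reports publish
#' (estimated coverage and the standard deviation of estimated cluster
#' coverages) by simulating complete two-stage surveys: for each area,
#' `k` latent cluster coverages from the chosen model and binomial
#' cluster counts of size `m`. Used as the synthetic test bed for the
#' between-cluster variance estimator, which should recover the
#' generating `sigma^2` on average.
#'
#' @param method `"hedt"` (beta-binomial), `"pezzoli"`
#'   (binomial-scaled) or `"srs"` (no clustering).
#' @param p True coverage shared by all areas.
#' @param clustering An [clustering_spec()] (ignored for `"srs"`).
#' @param n_areas Number of supervision areas to simulate.
#' @param k,m Clusters per area and subjects per cluster.
#' @return A data frame in the survey-summary schema, one row per area,
#'   with `s` filled and `se` empty.
#' @examples
#' set.seed(1)
#' simulate_survey_summaries("hedt", p = 0.8,
#'                           clustering = clustering_spec(rho = 0.1),
#'                           n_areas = 5, k = 10, m = 10)
#' @export
simulate_survey_summaries <- function(method, p, clustering = NULL, n_areas,
                                      k, m) {
  method <- match.arg(method, c("hedt", "pezzoli", "srs"))
  stopifnot(n_areas >= 1, k >= 2, m >= 1)
  ## draw all areas at once: k * n_areas clusters
  sim <- sample_total(method, k, m, p, clustering, n_draws = n_areas,
                      latent = TRUE)
  phat_j <- sim$counts / m                      # k x n_areas
  data.frame(area_id = sprintf("area%04d", seq_len(n_areas)),
             p_hat = colMeans(phat_j),
             s = apply(phat_j, 2, stats::sd),
             se = NA_real_,
             k = k, m = m, rho_hat = NA_real_)
}

#' Write a synthetic survey-summary fixture to CSV
#'
#' Convenience wrapper around [simulate_survey_summaries()] that seeds
#' the generator and writes a schema-conformant CSV, so the same seed
#' always produces byte-identical files.
#'
#' @inheritParams simulate_survey_summaries
#' @param path Output CSV path.
#' @param seed Integer seed.
#' @return The simulated data frame, invisibly.
#' @export
generate_fixture <- function(path, method, p, clustering = NULL, n_areas,
                             k, m, seed) {
  set.seed(seed)
  df <- simulate_survey_summaries(method, p, clustering, n_areas, k, m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}
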