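#' Analysis configuration
#'
#' Collects the fixed analysis constants used throughout the pipeline, with
#' the defaults used for clinical-style recordings. Every numeric is echoed
#' into output metadata by the writers so a run is self-describing.
#'
#' @param target_rate_hz sampling rate after preprocessing (Hz).
#' @param pre_window_ms pre-stimulation window used for surrogates, ms.
#' @param post_window_ms post-stimulation window searched for responses, ms.
#' @param ll_window_ms line-length integration window, ms.
#' @param artifact_window_ms stimulation-artifact interpolation window, ms
#'   (must lie in 10-15 ms).
#' @param lag_ms maximal lag for centroid cross-correlation, ms.
#' @param n_trial_surrogates surrogate count for the single-trial null.
#' @param n_centroid_surrogates surrogate re-computations per centroid.
#' @param n_exi_surrogates surrogate stimulation-response curves.
#' @param percentile one-sided significance percentile (0-100).
#' @param fdr_alpha false-discovery-rate level for connection-level tests.
#' @param distance_mm local/long-range distance threshold.
#' @param latency_ms short/long-latency threshold.
#' @param min_trials minimum trials for a complete measurement.
#' @param outlier_factor multiple of the median line length beyond which a
#'   trial is flagged as artifactual.
#' @param outlier_mode `"exclude"` drops flagged trials from all counts;
#'   `"flag"` only marks them.
#'
#' @return A list of class `cf_config`.
#' @export
cf_config <- function(target_rate_hz = 500,
                      pre_window_ms = 600,
                      post_window_ms = 500,
                      ll_window_ms = 250,
                      artifact_window_ms = 12,
                      lag_ms = 10,
                      n_trial_surrogates = 400,
                      n_centroid_surrogates = 200,
                      n_exi_surrogates = 200,
                      percentile = 95,
                      fdr_alpha = 0.05,
                      distance_mm = 25,
                      latency_ms = 65,
                      min_trials = 5,
                      outlier_factor = 4,
                      outlier_mode = c("exclude", "flag")) {
  outlier_mode <- match.arg(outlier_mode)
  cfg <- list(
    target_rate_hz = target_rate_hz,
    pre_window_ms = pre_window_ms,
    post_window_ms = post_window_ms,
    ll_window_ms = ll_window_ms,
    artifact_window_ms = artifact_window_ms,
    lag_ms = lag_ms,
    n_trial_surrogates = n_trial_surrogates,
    n_centroid_surrogates = n_centroid_surrogates,
    n_exi_surrogates = n_exi_surrogates,
    percentile = percentile,
    fdr_alpha = fdr_alpha,
    distance_mm = distance_mm,
    latency_ms = latency_ms,
    min_trials = min_trials,
    outlier_factor = outlier_factor,
    outlier_mode = outlier_mode
  )
  windows <- c(target_rate_hz, pre_window_ms, post_window_ms, ll_window_ms,
               artifact_window_ms, lag_ms)
  if (any(!is.finite(windows)) || any(windows <= 0))
    stop("all window lengths and rates must be positive", call. = FALSE)
  if (artifact_window_ms < 10 || artifact_window_ms > 15)
    stop("artifact_window_ms must lie within 10-15 ms", call. = FALSE)
  if (percentile <= 50 || percentile >= 100)
    stop("percentile must lie in (50, 100)", call. = FALSE)
  class(cfg) <- "cf_config"
  cfg
}

# sample counts at the analysis rate
.cfg_samples <- function(cfg) {
  sf <- cfg$target_rate_hz
  list(
    sf = sf,
    pre = round(cfg$pre_window_ms / 1000 * sf),
    post = round(cfg$post_window_ms / 1000 * sf),
    ll = round(cfg$ll_window_ms / 1000 * sf),
    offset = round(cfg$artifact_window_ms / 1000 * sf),
    lag = round(cfg$lag_ms / 1000 * sf)
  )
}

# analysis-window column indices inside a post-stimulation epoch
.analysis_cols <- function(cfg) {
  s <- .cfg_samples(cfg)
  (s$offset + 1):(s$offset + s$ll)
}

.with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
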