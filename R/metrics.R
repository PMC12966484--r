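# ---- connection-level metrics ----

#' Signaling probability
#'
#' The fraction of delivered stimulations that evoked a significant
#' single-trial response: `P = n_significant / n_stims`.
#'
#' @param decisions logical vector of single-trial significance decisions
#'   (one per delivered stimulation).
#' @return list: `n_stims`, `n_significant`, `P`. Zero stimulations give
#'   `P = NA` (undefined, not 0).
#' @export
signaling_probability <- function(decisions) {
  n <- length(decisions)
  k <- sum(decisions)
  list(n_stims = n, n_significant = k,
       P = if (n == 0) NA_real_ else k / n)
}

#' Directionality index
#'
#' `DI_AB = (P_AB - P_BA) / max(P_AB, P_BA)`. `DI -> 0` indicates
#' bidirectional signaling, `+1` a pure efference (solely sending), `-1` a
#' pure afference (solely receiving); `|DI| = 0.5` already means a doubling
#' of signaling in one direction. Antisymmetric: `DI_AB = -DI_BA`. When
#' both probabilities are 0 the index is undefined and `NA` is returned
#' (a 0 would assert bidirectionality of a silent pair). Vectorised.
#'
#' @param p_ab,p_ba signaling probabilities in `[0, 1]`.
#' @return numeric vector in `[-1, 1]`, `NA` where `max(P_AB, P_BA) = 0`.
#' @export
directionality_index <- function(p_ab, p_ba) {
  if (any(c(p_ab, p_ba) < 0 | c(p_ab, p_ba) > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mx <- pmax(p_ab, p_ba)
  out <- (p_ab - p_ba) / mx
  out[mx == 0] <- NA_real_
  out
}

#' Classify a connection by distance and latency
#'
#' Three connection categories: `local` (within `distance_mm` of the
#' stimulated electrode, same hemisphere and same brain region),
#' `long_short` (beyond `distance_mm`, latency at most `latency_ms`) and
#' `long_long` (beyond `distance_mm`, latency above `latency_ms`).
#' Short-distance pairs spanning regions, and long-range connections with
#' missing latency, are `unclassified`. Vectorised.
#'
#' @param distance_mm inter-electrode distance (mm).
#' @param latency_ms signaling latency (ms); may be `NA`.
#' @param same_region,same_hemisphere logicals.
#' @param cfg a [cf_config()] carrying the 25 mm / 65 ms thresholds.
#' @return character vector of classes.
#' @export
classify_connection <- function(distance_mm, latency_ms, same_region,
                                same_hemisphere = TRUE,
                                cfg = cf_config()) {
  n <- length(distance_mm)
  latency_ms <- rep_len(latency_ms, n)
  same_region <- rep_len(same_region, n)
  same_hemisphere <- rep_len(same_hemisphere, n)
  out <- rep("unclassified", n)
  local <- distance_mm < cfg$distance_mm & same_region & same_hemisphere
  long <- distance_mm >= cfg$distance_mm
  out[local] <- "local"
  out[long & !is.na(latency_ms) & latency_ms <= cfg$latency_ms] <- "long_short"
  out[long & !is.na(latency_ms) & latency_ms > cfg$latency_ms] <- "long_long"
  out
}

#' Response magnitude of a connection
#'
#' The line length of the pointwise average of at least `min_trials`
#' (default 5) significant single-trial responses, over the analysis
#' window. Fewer trials give `NA` with the count attached.
#'
#' @param post matrix of post-stimulation epochs of the significant trials.
#' @param cfg a [cf_config()].
#' @return line length of the average waveform, or `NA` with
#'   `attr(, "n")` = trial count.
#' @export
response_magnitude <- function(post, cfg = cf_config()) {
  s <- .cfg_samples(cfg)
  n <- if (is.null(dim(post))) as.integer(!is.null(post)) else nrow(post)
  if (n < cfg$min_trials) return(structure(NA_real_, n = n))
  avg <- colMeans(post)
  structure(line_length(avg[.analysis_cols(cfg)], s$sf), n = n)
}

.trapz <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Build a stimulation-response curve
#'
#' Response magnitude per stimulation-intensity level for one connection
#' and vigilance state: at each level with at least `min_trials` trials
#' (complete levels), the line length of the average post-stimulation
#' signal. Intensities are normalised so 0.2 mA maps to 0 and 12 mA to 1.
#'
#' @param post matrix of post-stimulation epochs.
#' @param intensity_ma per-trial stimulation intensity (mA).
#' @param cfg a [cf_config()].
#' @return data.frame per level: `intensity_ma`, `norm_intensity`, `n`,
#'   `magnitude`, `complete`.
#' @export
sr_curve <- function(post, intensity_ma, cfg = cf_config()) {
  s <- .cfg_samples(cfg)
  cols <- .analysis_cols(cfg)
  levels_ma <- sort(unique(intensity_ma))
  rows <- lapply(levels_ma, function(I) {
    sel <- intensity_ma == I
    n <- sum(sel)
    mag <- if (n >= cfg$min_trials)
      line_length(colMeans(post[sel, cols, drop = FALSE]), s$sf)
    else NA_real_
    data.frame(intensity_ma = I,
               norm_intensity = (I - 0.2) / (12 - 0.2),
               n = n, magnitude = mag, complete = n >= cfg$min_trials)
  })
  do.call(rbind, rows)
}

#' Excitability index
#'
#' The area under the normalised stimulation-response curve: response
#' magnitudes are normalised to `[0, 1]` by the maximal magnitude across
#' complete levels in wake (`wake_max`), intensities to `[0, 1]` over the
#' 0.2-12 mA protocol range, and the trapezoidal area over the available
#' complete levels is clipped to `[0, 1]`. `ExI -> 1` is maximal
#' sensitivity to minimal intensity, `~0.5` a linear increase over the full
#' range, `-> 0` non-excitable. With surrogate curves supplied, the ExI is
#' significant when it exceeds their 95th percentile.
#'
#' @param curve data.frame from [sr_curve()] (or with columns
#'   `norm_intensity`, `magnitude`, `complete`).
#' @param wake_max normalisation anchor: maximal magnitude across complete
#'   wake levels of the same connection. Defaults to the maximum of this
#'   curve (appropriate when the curve is the wake curve).
#' @param surrogate_exis optional numeric vector of surrogate excitability
#'   indices ([surrogate_exi()]); enables the significance decision.
#' @param cfg a [cf_config()].
#' @return list: `exi` (`NA` with a reason if fewer than 2 complete
#'   levels), `significant` (`NA` without surrogates), `n_levels`,
#'   `wake_max`.
#' @export
excitability_index <- function(curve, wake_max = NULL,
                               surrogate_exis = NULL, cfg = cf_config()) {
  cc <- curve[curve$complete & !is.na(curve$magnitude), , drop = FALSE]
  if (nrow(cc) < 2)
    return(list(exi = structure(NA_real_, reason = "fewer than 2 complete levels"),
                significant = NA, n_levels = nrow(cc), wake_max = wake_max))
  if (is.null(wake_max)) wake_max <- max(cc$magnitude)
  if (!is.finite(wake_max))
    return(list(exi = structure(NA_real_, reason = "invalid wake maximum"),
                significant = NA, n_levels = nrow(cc), wake_max = wake_max))
  y <- if (wake_max <= 0) rep(0, nrow(cc)) else   # zero curve: non-excitable
    pmin(1, pmax(0, cc$magnitude / wake_max))
  x <- cc$norm_intensity
  exi <- min(1, max(0, .trapz(x, y)))
  sig <- if (is.null(surrogate_exis)) NA else
    exi > quantile(surrogate_exis, cfg$percentile / 100, names = FALSE)
  list(exi = exi, significant = sig, n_levels = nrow(cc),
       wake_max = wake_max)
}

#' Surrogate excitability indices
#'
#' Builds surrogate stimulation-response curves from baseline epochs with
#' the same number of trials per intensity level as the observed curve
#' (average of as many random baseline epochs, line length, normalised by
#' the observed wake maximum), and returns their excitability indices.
#'
#' @param curve observed curve from [sr_curve()].
#' @param baseline_epochs matrix of baseline epochs for the channel.
#' @param wake_max normalisation anchor of the observed connection.
#' @param n number of surrogate curves (default `cfg$n_exi_surrogates`).
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return numeric vector of `n` surrogate ExI values.
#' @export
surrogate_exi <- function(curve, baseline_epochs, wake_max, n = NULL,
                          cfg = cf_config(), seed = 1) {
  if (is.null(n)) n <- cfg$n_exi_surrogates
  s <- .cfg_samples(cfg)
  cols <- .analysis_cols(cfg)
  cc <- curve[curve$complete, , drop = FALSE]
  m <- nrow(baseline_epochs)
  .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      mags <- vapply(cc$n, function(nk) {
        pick <- sample(m, nk, replace = TRUE)
        line_length(colMeans(baseline_epochs[pick, cols, drop = FALSE]), s$sf)
      }, numeric(1))
      sur <- data.frame(norm_intensity = cc$norm_intensity, magnitude = mags,
                        complete = TRUE)
      excitability_index(sur, wake_max = wake_max, cfg = cfg)$exi
    }, numeric(1))
  })
}
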