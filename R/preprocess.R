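# ---- preprocessing: artifact interpolation, filtering, epoching ----

#' Interpolate stimulation artifacts
#'
#' Replaces the samples in `[T0, T0 + window_ms]` after each stimulation by
#' the straight line joining the samples bracketing the window. All other
#' samples are untouched (bit-identical). Events too close to a recording
#' edge to have bracketing samples are dropped with a warning.
#'
#' @param signal numeric vector or channels-x-samples matrix.
#' @param onsets_s stimulation onset times (s).
#' @param sampling_rate_hz sampling rate of `signal`.
#' @param window_ms interpolation window, 10-15 ms (default 12).
#' @return object of the same shape with artifact windows interpolated;
#'   the number of dropped edge events in `attr(, "dropped_events")`.
#' @export
interpolate_artifact <- function(signal, onsets_s, sampling_rate_hz,
                                 window_ms = 12) {
  if (window_ms < 10 || window_ms > 15)
    stop("window_ms must lie within 10-15 ms", call. = FALSE)
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else signal
  n <- ncol(x)
  w <- round(window_ms / 1000 * sampling_rate_hz)
  dropped <- 0L
  for (t0 in onsets_s) {
    i0 <- round(t0 * sampling_rate_hz) + 1
    i1 <- i0 + w
    if (i0 - 1 < 1 || i1 + 1 > n) {
      dropped <- dropped + 1L
      next
    }
    frac <- (seq(i0, i1) - (i0 - 1)) / (i1 + 1 - (i0 - 1))
    x[, i0:i1] <- x[, i0 - 1] %o% (1 - frac) + x[, i1 + 1] %o% frac
  }
  if (dropped > 0)
    warning(dropped, " event(s) at the signal edge were not interpolated")
  out <- if (vec) x[1, ] else x
  attr(out, "dropped_events") <- dropped
  out
}

# zero-phase (forward-backward) IIR filtering with odd-reflection edge
# padding to suppress end transients
.filtfilt <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  np <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= np + 1) stop("signal too short to filter", call. = FALSE)
  y <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- .iir_filter(b, a, y)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

# zero-phase bandpass + notch comb; operates on one channel
.filter_channel <- function(x, sf) {
  ny <- sf / 2
  bp <- signal::butter(4, c(0.5, min(200, 0.95 * ny)) / ny, type = "pass")
  x <- .filtfilt(bp$b, bp$a, x)
  for (f0 in c(50, 100, 150, 200)) {
    if (f0 + 2 >= ny) break
    bs <- signal::butter(2, c(f0 - 2, f0 + 2) / ny, type = "stop")
    x <- .filtfilt(bs$b, bs$a, x)
  }
  x
}

#' Bandpass/notch filter and resample to the analysis rate
#'
#' Applies a zero-phase 0.5-200 Hz Butterworth bandpass and second-order
#' notches at 50 Hz and harmonics, then polyphase-resamples to
#' `target_rate_hz` (default 500 Hz). Zero-phase (forward-backward)
#' filtering is used so response latencies are preserved. Optionally each
#' channel is rescaled by a robust amplitude estimate (median absolute
#' deviation) of its stimulation-free baseline so channels share a scale.
#'
#' @param signal numeric vector or channels-x-samples matrix.
#' @param sampling_rate_hz input rate; must be >= `target_rate_hz`.
#' @param target_rate_hz output rate (default 500 Hz).
#' @param rescale logical; divide each channel by the MAD of its baseline.
#' @param baseline_windows data.frame (`start_s`, `end_s`) of
#'   stimulation-free windows used for the rescaling estimate; `NULL` uses
#'   the whole trace.
#' @return filtered signal at `target_rate_hz`; per-channel scale factors in
#'   `attr(, "scale")` when `rescale = TRUE`.
#' @export
filter_resample <- function(signal, sampling_rate_hz, target_rate_hz = 500,
                            rescale = FALSE, baseline_windows = NULL) {
  if (sampling_rate_hz < target_rate_hz)
    stop("input rate must be >= target rate", call. = FALSE)
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else signal
  frac <- .rate_fraction(target_rate_hz, sampling_rate_hz)
  out <- NULL
  for (ch in seq_len(nrow(x))) {
    y <- .filter_channel(x[ch, ], sampling_rate_hz)
    y <- if (sampling_rate_hz == target_rate_hz) y else
      signal::resample(y, frac[1], frac[2])
    if (is.null(out)) out <- matrix(0, nrow(x), length(y))
    out[ch, ] <- y
  }
  rownames(out) <- rownames(x)
  scales <- NULL
  if (rescale) {
    mask <- .baseline_mask(ncol(out), target_rate_hz, baseline_windows)
    scales <- apply(out[, mask, drop = FALSE], 1, mad)
    scales[scales == 0] <- 1
    out <- out / scales
  }
  res <- if (vec) out[1, ] else out
  attr(res, "scale") <- scales
  res
}

.rate_fraction <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

.baseline_mask <- function(n, sf, windows) {
  if (is.null(windows)) return(rep(TRUE, n))
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(windows))) {
    a <- max(1, round(windows$start_s[i] * sf) + 1)
    b <- min(n, round(windows$end_s[i] * sf))
    if (b >= a) mask[a:b] <- TRUE
  }
  if (!any(mask)) rep(TRUE, n) else mask
}

#' Preprocess a raw recording
#'
#' Full preprocessing chain: stimulation-artifact interpolation (at the
#' native rate), bandpass + notch filtering, robust per-channel rescaling
#' against the stimulation-free baseline, and resampling to the analysis
#' rate from `cfg`.
#'
#' @param recording a `bipolar_recording` (e.g. from [simulate_session()]).
#' @param events stimulation events data.frame.
#' @param cfg a [cf_config()].
#' @return preprocessed `bipolar_recording` at `cfg$target_rate_hz`.
#' @export
preprocess_recording <- function(recording, events, cfg = cf_config()) {
  sf <- recording$sampling_rate
  x <- interpolate_artifact(recording$signal, events$onset_s, sf,
                            cfg$artifact_window_ms)
  bw <- attr(events, "baseline_windows")
  x <- filter_resample(x, sf, cfg$target_rate_hz, rescale = TRUE,
                       baseline_windows = bw)
  out <- recording
  out$signal <- x
  out$sampling_rate <- cfg$target_rate_hz
  attr(out, "truth") <- attr(recording, "truth")
  attr(out, "baseline_windows") <- bw
  out
}

#' Extract peri-stimulation trials
#'
#' Builds one trial per (stimulation event, recording channel) with the
#' recording channel different from the stimulated pair. Each trial holds a
#' pre-stimulation window (`cfg$pre_window_ms` before T0) and a
#' post-stimulation window (`cfg$post_window_ms` from T0), contiguous at
#' T0, and is tagged with the vigilance state at its onset (`"unknown"` if
#' no segment covers it). Trials overlapping a recording edge are dropped
#' and counted.
#'
#' @param recording preprocessed `bipolar_recording` at the analysis rate.
#' @param events stimulation events data.frame.
#' @param vigilance a [vigilance_track()] or `NULL`.
#' @param cfg a [cf_config()].
#' @return list of class `trial_set`: `meta` (event_id, stim_pair, channel,
#'   onset_s, intensity_ma, block_kind, state), `pre` and `post` matrices
#'   (one row per trial), `sampling_rate`, `n_dropped`.
#' @export
epoch_trials <- function(recording, events, vigilance = NULL,
                         cfg = cf_config()) {
  s <- .cfg_samples(cfg)
  stopifnot(recording$sampling_rate == s$sf)
  x <- recording$signal
  n <- ncol(x)
  chans <- rownames(x)
  states <- if (is.null(vigilance)) rep("unknown", nrow(events)) else
    state_at(vigilance, events$onset_s)
  i0 <- round(events$onset_s * s$sf) + 1
  keep <- i0 - s$pre >= 1 & i0 + s$post - 1 <= n
  n_dropped <- sum(!keep)
  ev <- events[keep, , drop = FALSE]
  i0 <- i0[keep]
  states <- states[keep]
  meta <- list(); pre <- list(); post <- list()
  for (ch in chans) {
    other <- ev$stim_pair != ch
    if (!any(other)) next
    ii <- i0[other]
    meta[[ch]] <- data.frame(
      event_id = ev$event_id[other], stim_pair = ev$stim_pair[other],
      channel = ch, onset_s = ev$onset_s[other],
      intensity_ma = ev$intensity_ma[other],
      block_kind = ev$block_kind[other], state = states[other],
      stringsAsFactors = FALSE)
    pre[[ch]] <- t(vapply(ii, function(i) x[ch, (i - s$pre):(i - 1)],
                          numeric(s$pre)))
    post[[ch]] <- t(vapply(ii, function(i) x[ch, i:(i + s$post - 1)],
                           numeric(s$post)))
  }
  structure(list(meta = do.call(rbind, meta),
                 pre = do.call(rbind, pre), post = do.call(rbind, post),
                 sampling_rate = s$sf, n_dropped = n_dropped),
            class = "trial_set")
}

#' Sample surrogate epochs from stimulation-free data
#'
#' Draws `n` trial-shaped epochs (post-window length) from the
#' stimulation-free portions of one channel: all samples at least one
#' pre-window before and 1.5 s after any stimulation onset. Onsets are
#' sampled with replacement, so epochs may overlap (a 5-min baseline cannot
#' host hundreds of disjoint windows).
#'
#' @param recording preprocessed `bipolar_recording`.
#' @param events stimulation events data.frame.
#' @param channel channel name.
#' @param n number of surrogate epochs.
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return n x post-window-samples matrix of surrogate epochs.
#' @export
sample_baseline_epochs <- function(recording, events, channel, n,
                                   cfg = cf_config(), seed = 1) {
  s <- .cfg_samples(cfg)
  x <- recording$signal[channel, ]
  len <- length(x)
  free <- rep(TRUE, len)
  for (t0 in events$onset_s) {
    a <- max(1, round((t0 - cfg$pre_window_ms / 1000) * s$sf))
    b <- min(len, round((t0 + 1.5) * s$sf))
    if (b >= a) free[a:b] <- FALSE
  }
  cs <- cumsum(as.integer(free))
  w <- s$post
  if (len <= w)
    stop(sprintf(
      "insufficient stimulation-free baseline: need at least %.1f s free",
      w / s$sf), call. = FALSE)
  starts <- seq_len(len - w + 1)
  ok <- (cs[starts + w - 1] - c(0, cs)[starts]) == w
  starts <- starts[ok]
  if (length(starts) < 1)
    stop(sprintf(
      "insufficient stimulation-free baseline: need at least %.1f s free",
      w / s$sf), call. = FALSE)
  .with_seed(seed, picks <- sample(starts, n, replace = TRUE))
  t(vapply(picks, function(i) x[i:(i + w - 1)], numeric(w)))
}
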