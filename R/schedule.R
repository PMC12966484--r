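#' The 14-level stimulation-response intensity protocol (mA)
#'
#' Fourteen single-pulse intensities spanning 0.2 to 12 mA used by the
#' stimulation-response (excitability) blocks.
#'
#' @export
sr_intensities <- function() {
  c(0.2, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12)
}

# truncated-Gaussian inter-stimulus intervals: mean 4.5 s, SD 0.2 s, floor 3 s
.draw_isi <- function(n, mean_s = 4.5, sd_s = 0.2, floor_s = 3) {
  pmax(floor_s, rnorm(n, mean_s, sd_s))
}

#' Build an hourly-block stimulation schedule
#'
#' Emulates the clinical mapping protocol: each hourly block holds (1) a
#' 5-minute stimulation-free baseline, (2) a mapping block in which every
#' electrode is stimulated `mapping_reps` times at 3 mA in randomized order,
#' and (3) a stimulation-response block for `sr_electrodes` with the 14
#' protocol intensities repeated `sr_reps` times each, in randomized order.
#' Inter-stimulus intervals are Gaussian with mean 4.5 s and SD 0.2 s,
#' truncated at 3 s.
#'
#' @param duration_h session duration in hours (>= 1 full block).
#' @param electrodes character vector of stimulable electrode names (>= 2).
#' @param mapping_reps repetitions per electrode in the mapping block (3-5).
#' @param sr_electrodes subset of `electrodes` receiving the
#'   stimulation-response protocol (may be empty).
#' @param sr_reps repetitions per intensity level (default 3).
#' @param mapping_intensity_ma fixed mapping intensity (default 3 mA).
#' @param baseline_min baseline duration per block in minutes (>= 5).
#' @param pulse_width_ms stimulus pulse width (default 1 ms biphasic).
#' @param seed integer seed for ordering and interval jitter.
#'
#' @return data.frame of stimulation events with columns `onset_s`,
#'   `stim_pair`, `intensity_ma`, `pulse_width_ms`, `block_id`,
#'   `block_kind` (`baseline` blocks carry no events); the stimulation-free
#'   baseline windows are attached as `attr(, "baseline_windows")`.
#' @export
build_schedule <- function(duration_h, electrodes, mapping_reps = 3,
                           sr_electrodes = character(), sr_reps = 3,
                           mapping_intensity_ma = 3, baseline_min = 5,
                           pulse_width_ms = 1, seed = 1) {
  stopifnot(length(electrodes) >= 2)
  if (mapping_reps < 3 || mapping_reps > 5)
    stop("mapping_reps must be 3-5", call. = FALSE)
  if (baseline_min < 5)
    stop("baseline must be at least 5 minutes", call. = FALSE)
  if (length(sr_electrodes) && !all(sr_electrodes %in% electrodes))
    stop("sr_electrodes must be a subset of electrodes", call. = FALSE)
  n_map <- length(electrodes) * mapping_reps
  n_sr <- length(sr_electrodes) * length(sr_intensities()) * sr_reps
  block_need_s <- baseline_min * 60 + (n_map + n_sr) * 4.5
  if (duration_h * 3600 < block_need_s)
    stop(sprintf(
      "schedule infeasible: one block needs %.1f min but duration is %.1f min",
      block_need_s / 60, duration_h * 60), call. = FALSE)
  block_period_s <- max(3600, block_need_s)
  n_blocks <- max(1L, floor(duration_h * 3600 / block_period_s))
  events <- vector("list", n_blocks)
  baselines <- vector("list", n_blocks)
  .with_seed(seed, {
    for (b in seq_len(n_blocks)) {
      t0 <- (b - 1) * block_period_s
      baselines[[b]] <- data.frame(start_s = t0, end_s = t0 + baseline_min * 60)
      stims <- sample(rep(electrodes, mapping_reps))
      kinds <- rep("mapping", n_map)
      ints <- rep(mapping_intensity_ma, n_map)
      if (n_sr > 0) {
        sr_grid <- expand.grid(stim = sr_electrodes,
                               intensity = sr_intensities(),
                               rep = seq_len(sr_reps),
                               stringsAsFactors = FALSE)
        ord <- sample(nrow(sr_grid))
        stims <- c(stims, sr_grid$stim[ord])
        kinds <- c(kinds, rep("sr_curve", n_sr))
        ints <- c(ints, sr_grid$intensity[ord])
      }
      onsets <- t0 + baseline_min * 60 + cumsum(.draw_isi(n_map + n_sr))
      events[[b]] <- data.frame(
        onset_s = onsets, stim_pair = stims, intensity_ma = ints,
        pulse_width_ms = pulse_width_ms, block_id = b, block_kind = kinds,
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, events)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out$event_id <- seq_len(nrow(out))
  attr(out, "baseline_windows") <- do.call(rbind, baselines)
  out
}

#' Build a focused stimulation schedule
#'
#' A lower-level schedule constructor for targeted experiments: a single
#' stimulation-free baseline followed by `n` stimulations of each listed
#' electrode (interleaved in randomized order) at a fixed intensity, with
#' the protocol's truncated-Gaussian inter-stimulus intervals. Used by the
#' recovery experiments where the trial count per connection, not the
#' hourly clinical timing, is the quantity of interest.
#'
#' @param electrodes character vector of stimulated electrode names.
#' @param n stimulations per electrode.
#' @param intensity_ma stimulation intensity (default 3 mA mapping level).
#' @param baseline_s leading stimulation-free baseline in seconds.
#' @param block_kind label for the events (default `"mapping"`).
#' @param seed integer seed.
#'
#' @return events data.frame as in [build_schedule()].
#' @export
schedule_trials <- function(electrodes, n, intensity_ma = 3,
                            baseline_s = 60, block_kind = "mapping", seed = 1) {
  stopifnot(length(electrodes) >= 1, n >= 1)
  grid <- expand.grid(stim = electrodes, rep = seq_len(n),
                      stringsAsFactors = FALSE)
  if (length(intensity_ma) == 1) {
    grid$intensity <- intensity_ma
  } else {
    grid$intensity <- rep_len(intensity_ma, nrow(grid))
  }
  .with_seed(seed, {
    ord <- sample(nrow(grid))
    onsets <- baseline_s + cumsum(.draw_isi(nrow(grid)))
  })
  out <- data.frame(onset_s = onsets, stim_pair = grid$stim[ord],
                    intensity_ma = grid$intensity[ord],
                    pulse_width_ms = 1, block_id = 1L, block_kind = block_kind,
                    stringsAsFactors = FALSE)
  out$event_id <- seq_len(nrow(out))
  attr(out, "baseline_windows") <- data.frame(start_s = 0, end_s = baseline_s)
  out
}

#' Build a vigilance-state track
#'
#' @param segments data.frame with columns `start_s`, `end_s`, `state`
#'   (states among W, N1, N2, N3, R). Segments must be ordered and
#'   non-overlapping.
#' @return validated data.frame of class `vigilance_track`.
#' @export
vigilance_track <- function(segments) {
  stopifnot(all(c("start_s", "end_s", "state") %in% names(segments)))
  if (!all(segments$state %in% c("W", "N1", "N2", "N3", "R")))
    stop("states must be among W, N1, N2, N3, R", call. = FALSE)
  if (any(segments$end_s <= segments$start_s))
    stop("segments must have positive duration", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(segments$start_s[-1] < segments$end_s[-nrow(segments)]))
    stop("segments must be ordered and non-overlapping", call. = FALSE)
  class(segments) <- c("vigilance_track", "data.frame")
  segments
}

#' Look up the vigilance state at given times
#'
#' @param track a [vigilance_track()].
#' @param times_s numeric vector of times (s).
#' @return character vector; `"unknown"` where no segment covers the time.
#' @export
state_at <- function(track, times_s) {
  out <- rep("unknown", length(times_s))
  for (i in seq_len(nrow(track))) {
    hit <- times_s >= track$start_s[i] & times_s < track$end_s[i]
    out[hit] <- track$state[i]
  }
  out
}
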