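# ---- synthetic iEEG session generator ----

# unit-SD 1/f-shaped Gaussian noise via spectral shaping; the FFT length is
# padded to the next highly composite number, then truncated
.pink_noise <- function(n, sf, floor_hz = 0.5) {
  m <- stats::nextn(n, c(2, 3))
  white <- rnorm(m)
  spec <- fft(white)
  freq <- seq(0, sf, length.out = m + 1)[seq_len(m)]
  freq[freq > sf / 2] <- sf - freq[freq > sf / 2]  # mirror to physical freq
  shape <- 1 / sqrt(pmax(freq, floor_hz))          # power ~ 1/f above floor
  shape[1] <- 0                                    # no DC
  x <- Re(fft(spec * shape, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

#' Biphasic evoked-response template
#'
#' A stereotyped cortical evoked waveform: two opposite-polarity
#' Gaussian-windowed deflections, an early sharp component peaking at
#' `latency_ms` and a later broader one of opposite sign peaking at
#' `late_factor * latency_ms`, emulating the two characteristic deflections
#' of a cortical response to single-pulse stimulation.
#'
#' @param t_s sample times relative to stimulation onset (s, >= 0).
#' @param latency_ms first-peak latency (ms).
#' @param amplitude first-peak amplitude (signal units); the first
#'   deflection is negative-going, as is conventional for these responses.
#' @param late_factor latency multiple of the second deflection.
#' @param ratio amplitude of the second deflection relative to the first.
#' @return numeric vector of the template evaluated at `t_s`.
#' @export
evoked_template <- function(t_s, latency_ms = 40, amplitude = 1,
                            late_factor = 2.5, ratio = 0.5) {
  l1 <- latency_ms / 1000
  w1 <- l1 / 3
  l2 <- late_factor * l1
  w2 <- 2 * w1
  amplitude * (-exp(-(t_s - l1)^2 / (2 * w1^2)) +
                 ratio * exp(-(t_s - l2)^2 / (2 * w2^2)))
}

#' Simulate a stimulation session
#'
#' Renders a multichannel bipolar iEEG recording for a ground-truth network
#' and a stimulation schedule. Background activity is 1/f-shaped noise plus
#' a 50 Hz line component per channel. At each stimulation, every channel
#' connected to the stimulated electrode independently receives, with
#' probability `true_probability x state gain x intensity sigmoid`, the
#' stereotyped evoked waveform of [evoked_template()] scaled by the
#' connection amplitude (with multiplicative lognormal trial-to-trial
#' jitter and +/-5 ms latency jitter) and by the same state/intensity
#' factors. A brief square stimulation artifact (8 ms, 20x noise SD,
#' attenuated with distance from the stimulated electrode) is added to all
#' channels. Identical seeds give bit-identical output.
#'
#' @param network a [make_network()] ground-truth network.
#' @param schedule events data.frame from [build_schedule()] or
#'   [schedule_trials()].
#' @param vigilance a [vigilance_track()]; `NULL` means wake throughout.
#' @param seed integer seed (required; the generator is deterministic).
#' @param sampling_rate_hz recording rate (default 1024 Hz).
#' @param noise_sd background noise standard deviation (signal units, uV).
#' @param line_amp amplitude of the 50 Hz line component relative to
#'   `noise_sd`.
#' @param amp_jitter_sdlog lognormal sigma of trial-to-trial amplitude
#'   variability.
#' @param latency_jitter_ms half-width of the uniform latency jitter.
#' @param artifact_ms,artifact_gain stimulation-artifact duration and
#'   amplitude (in noise SDs); attenuation with distance d is exp(-d/30 mm).
#'
#' @return list of class `bipolar_recording`: `signal` (channels x samples),
#'   `sampling_rate`, `channel_table`, `start_time`, `noise_sd`, plus a
#'   ground-truth trial table in `attr(, "truth")` (one row per stimulation
#'   x connected channel: injected flag, realised amplitude and latency).
#' @export
simulate_session <- function(network, schedule, vigilance = NULL, seed,
                             sampling_rate_hz = 1024, noise_sd = 10,
                             line_amp = 0.5, amp_jitter_sdlog = 0.25,
                             latency_jitter_ms = 5,
                             artifact_ms = 8, artifact_gain = 20) {
  stopifnot(inherits(network, "gt_network"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  elec <- network$electrodes
  if (!all(schedule$stim_pair %in% elec$name))
    stop("schedule references unknown electrodes", call. = FALSE)
  sf <- sampling_rate_hz
  dur_s <- max(schedule$onset_s) + 2
  n <- ceiling(dur_s * sf)
  nc <- nrow(elec)
  if (is.null(vigilance))
    vigilance <- vigilance_track(
      data.frame(start_s = 0, end_s = dur_s + 1, state = "W"))
  states <- state_at(vigilance, schedule$onset_s)
  groups <- .gain_group(states)
  conns <- network$connections
  d <- network$distances
  truth <- list()
  sig <- matrix(0, nc, n)
  .with_seed(seed, {
    tsec <- seq_len(n) / sf
    for (ch in seq_len(nc)) {
      phase <- runif(1, 0, 2 * pi)
      sig[ch, ] <- noise_sd * .pink_noise(n, sf) +
        line_amp * noise_sd * sin(2 * pi * 50 * tsec + phase)
    }
    art_len <- round(artifact_ms / 1000 * sf)
    resp_len <- round(0.4 * sf)  # 400 ms template support
    t_resp <- (seq_len(resp_len) - 1) / sf
    for (k in seq_len(nrow(schedule))) {
      i0 <- round(schedule$onset_s[k] * sf) + 1
      # stimulation artifact on all channels, distance-attenuated
      att <- exp(-d[schedule$stim_pair[k], ] / 30)
      idx <- i0:min(n, i0 + art_len - 1)
      sig[, idx] <- sig[, idx] + artifact_gain * noise_sd * att
      # evoked responses on connected channels
      rows <- which(conns$from == schedule$stim_pair[k])
      for (r in rows) {
        ch <- match(conns$to[r], elec$name)
        g <- switch(groups[k], W = conns$gain_w[r],
                    NREM = conns$gain_nrem[r], REM = conns$gain_rem[r])
        s_int <- .intensity_gain(schedule$intensity_ma[k],
                                 conns$sigmoid_mid_ma[r],
                                 conns$sigmoid_slope_ma[r])
        p_eff <- min(1, conns$prob[r] * g * s_int)
        inject <- runif(1) < p_eff
        amp <- lat <- NA_real_
        if (inject) {
          amp <- conns$amplitude[r] * g * s_int *
            rlnorm(1, 0, amp_jitter_sdlog)
          lat <- conns$latency_ms[r] +
            runif(1, -latency_jitter_ms, latency_jitter_ms)
          w <- evoked_template(t_resp, latency_ms = lat, amplitude = amp)
          jdx <- i0:min(n, i0 + resp_len - 1)
          sig[ch, jdx] <- sig[ch, jdx] + w[seq_along(jdx)]
        }
        truth[[length(truth) + 1]] <- data.frame(
          event_id = schedule$event_id[k], channel = conns$to[r],
          stim_pair = schedule$stim_pair[k], state = states[k],
          injected = inject, amplitude = amp, latency_ms = lat,
          stringsAsFactors = FALSE)
      }
    }
  })
  rownames(sig) <- elec$name
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event_id = integer(), channel = character(),
               stim_pair = character(), state = character(),
               injected = logical(), amplitude = numeric(),
               latency_ms = numeric(), stringsAsFactors = FALSE)
  rec <- structure(list(signal = sig, sampling_rate = sf,
                        channel_table = elec, start_time = 0,
                        noise_sd = noise_sd),
                   class = "bipolar_recording")
  attr(rec, "truth") <- truth
  rec
}
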