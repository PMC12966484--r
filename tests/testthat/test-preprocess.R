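test_that("artifact interpolation restores degree-1 signals exactly", {
  sf <- 1000
  const <- rep(3, 1000)
  spiky <- const
  spiky[501:510] <- 100
  out <- interpolate_artifact(spiky, 0.5, sf, window_ms = 12)
  expect_equal(as.numeric(out), const, tolerance = 1e-12)
  ramp <- seq(0, 10, length.out = 1000)
  spiky <- ramp
  spiky[505] <- 50
  out <- interpolate_artifact(spiky, 0.5, sf, window_ms = 12)
  expect_equal(as.numeric(out), ramp, tolerance = 1e-12)
})

test_that("interpolation touches only the declared window", {
  set.seed(1)
  x <- rnorm(2000)
  out <- interpolate_artifact(x, 1, 1000, window_ms = 12)
  w <- 1001:1013  # T0 .. T0 + 12 ms inclusive
  expect_identical(out[-w], x[-w])
  expect_false(identical(out[w], x[w]))
  expect_error(interpolate_artifact(x, 1, 1000, window_ms = 20), "10-15")
  expect_warning(interpolate_artifact(x, 0, 1000), "edge")
})

test_that("stimulation artifacts are suppressed to near-background level", {
  # compare against an artifact-free twin of the same seed
  sched <- schedule_trials("A", 10, baseline_s = 20, seed = 11)
  with_art <- simulate_session(fx_network, sched, seed = 12)
  no_art <- simulate_session(fx_network, sched, seed = 12,
                             artifact_gain = 0)
  clean <- interpolate_artifact(with_art$signal, sched$onset_s, 1024)
  sf <- 1024
  w <- round(0.012 * sf)
  bg_sd <- sd(no_art$signal["B", 1:(15 * sf)])
  art_amp <- 20 * 10  # generator artifact amplitude before attenuation
  for (t0 in sched$onset_s) {
    i0 <- round(t0 * sf) + 1
    seg <- clean["B", i0:(i0 + w)] - no_art$signal["B", i0:(i0 + w)]
    # the interpolated trace deviates from the artifact-free twin by no
    # more than ordinary background excursions, far below the artifact
    expect_lt(max(abs(seg)), 4 * bg_sd)
    expect_lt(max(abs(seg)), art_amp / 4)
  }
})

test_that("filtering attenuates line noise and preserves the passband", {
  sf <- 1024
  t_s <- (0:(10 * sf - 1)) / sf
  rms <- function(x) sqrt(mean(x^2))
  mid <- function(x) x[round(length(x) * 0.2):round(length(x) * 0.8)]
  y50 <- filter_resample(sin(2 * pi * 50 * t_s), sf)
  expect_lt(rms(mid(y50)), 0.1)            # >= 20 dB at 50 Hz
  y10 <- filter_resample(sin(2 * pi * 10 * t_s), sf)
  expect_equal(rms(mid(y10)), 1 / sqrt(2), tolerance = 0.1)
  yz <- filter_resample(rep(0, 10 * sf), sf)
  expect_true(all(yz == 0))
  expect_equal(length(y10), 5 * 1000)      # exactly 500 Hz output
  expect_error(filter_resample(rnorm(100), 400), ">=")
})

test_that("the filter chain is idempotent in the passband", {
  t_s <- (0:(20 * 500 - 1)) / 500
  x0 <- sin(2 * pi * 5 * t_s) + 0.5 * sin(2 * pi * 12 * t_s) +
    0.3 * sin(2 * pi * 30 * t_s)
  x <- filter_resample(x0, 500)
  x2 <- filter_resample(x, 500)
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(x2[mid]) - rms(x[mid])) / rms(x[mid]), 0.01)
})

test_that("zero-phase filtering matches the reference implementation", {
  set.seed(3)
  x <- rnorm(5000)
  bt <- signal::butter(2, c(48, 52) / 512, "stop")
  ours <- corticoflow:::.filtfilt(bt$b, bt$a, x)
  ref <- signal::filtfilt(bt, x)
  mid <- 500:4500
  expect_gt(cor(ours[mid], ref[mid]), 0.999)
})

test_that("epoching yields one trial per event and non-stimulated channel", {
  el <- make_electrodes(paste0("E", 1:5), rep("r", 5))
  net <- make_network(el, NULL)
  sched <- schedule_trials("E1", 10, baseline_s = 10, seed = 4)
  rec <- simulate_session(net, sched, seed = 5)
  pre <- preprocess_recording(rec, sched)
  tr <- epoch_trials(pre, sched)
  expect_equal(nrow(tr$meta), 40)   # 10 events x 4 non-stimulated channels
  expect_equal(ncol(tr$pre), 300)   # 600 ms at 500 Hz
  expect_equal(ncol(tr$post), 250)  # 500 ms at 500 Hz
  expect_false(anyNA(tr$post))
})

test_that("edge trials are dropped and counted", {
  el <- make_electrodes(c("A", "B"), c("r", "r"))
  net <- make_network(el, NULL)
  sched <- schedule_trials("A", 3, baseline_s = 10, seed = 6)
  sched$onset_s[1] <- 0.1   # pre-window would start before the recording
  rec <- simulate_session(net, sched, seed = 7)
  pre <- preprocess_recording(rec, sched)
  tr <- epoch_trials(pre, sched)
  expect_equal(tr$n_dropped, 1)
  expect_equal(nrow(tr$meta), 2)
})

test_that("epochs are pure slices of the preprocessed signal", {
  tr <- fx_trials
  i <- 5
  ch <- tr$meta$channel[i]
  i0 <- round(tr$meta$onset_s[i] * 500) + 1
  slice <- fx_pre$signal[ch, (i0 - 300):(i0 + 249)]
  expect_equal(unname(c(tr$pre[i, ], tr$post[i, ])), unname(slice))
})

test_that("trials are tagged with the vigilance state at onset", {
  vig <- vigilance_track(data.frame(
    start_s = c(0, 100), end_s = c(100, 1e4), state = c("W", "N2")))
  tr <- epoch_trials(fx_pre, fx_schedule, vig)
  expect_setequal(unique(tr$meta$state), c("W", "N2"))
  expect_equal(tr$meta$state, ifelse(tr$meta$onset_s < 100, "W", "N2"))
})

test_that("baseline surrogate sampling stays clear of stimulations and errors when impossible", {
  ep <- sample_baseline_epochs(fx_pre, fx_schedule, "B", 50, seed = 8)
  expect_equal(dim(ep), c(50, 250))
  # all sampled windows lie inside the 60 s baseline or after the last event
  short <- fx_pre
  short$signal <- short$signal[, 1:200, drop = FALSE]
  expect_error(sample_baseline_epochs(short, fx_schedule, "B", 10),
               "insufficient")
})
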