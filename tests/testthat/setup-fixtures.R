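# Shared fixtures, built once per test run. Small on purpose: a
# two-electrode session with one strong (A->B) and one weak (B->A)
# connection, analysed end to end.

fx_electrodes <- make_electrodes(c("A", "B"), c("regA", "regB"),
                                 xyz = rbind(c(0, 0, 0), c(40, 0, 0)))

fx_network <- make_network(
  fx_electrodes,
  data.frame(from = c("A", "B"), to = c("B", "A"),
             prob = c(0.9, 0.3), stringsAsFactors = FALSE),
  amplitude = 50, latency_ms = 40)

fx_schedule <- schedule_trials(c("A", "B"), 40, baseline_s = 60, seed = 101)
fx_raw <- simulate_session(fx_network, fx_schedule, seed = 102)
fx_truth <- attr(fx_raw, "truth")
fx_cfg <- cf_config()
fx_pre <- preprocess_recording(fx_raw, fx_schedule, fx_cfg)
fx_trials <- epoch_trials(fx_pre, fx_schedule, NULL, fx_cfg)
fx_analysis <- analyze_session(fx_pre, fx_schedule, NULL, fx_cfg, seed = 103)

# analysis-window columns as configured by default (12 ms artifact offset,
# 250 ms width at 500 Hz)
.analysis_cols_test <- function() 7:131

# two-polarity synthetic trial set for centroid tests: half the trials carry
# a positive template, half its negation, plus weak noise
fx_polarity <- local({
  cfg <- cf_config()
  sf <- 500
  tpl <- evoked_template((0:249) / sf, latency_ms = 60, amplitude = 10)
  withr::with_seed(7, {
    up <- t(replicate(20, tpl + rnorm(250, 0, 0.5)))
    dn <- t(replicate(20, -tpl + rnorm(250, 0, 0.5)))
  })
  list(post = rbind(up, dn), template = tpl)
})
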