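# ---- simulation experiment drivers ----

#' Simulate and analyze one two-electrode connection pair
#'
#' Builds a two-electrode ground-truth network with directed probabilities
#' `(p_ab, p_ba)`, simulates a mapping session with `n_trials`
#' stimulations per electrode, runs the full preprocessing and detection
#' chain, and returns estimated against generative quantities. The two
#' electrodes are placed 40 mm apart in different regions.
#'
#' @param p_ab,p_ba true per-pulse response probabilities at 3 mA.
#' @param n_trials stimulations per electrode.
#' @param amplitude evoked first-peak amplitude (units of `noise_sd`
#'   multiples times 10; default 50 = 5x the background SD of 10).
#' @param baseline_s stimulation-free baseline for surrogates (s).
#' @param seed integer seed.
#' @param cfg a [cf_config()].
#' @return one-row data.frame: true and estimated P in both directions and
#'   the true and estimated directionality index.
#' @export
simulate_pair_recovery <- function(p_ab, p_ba, n_trials = 300,
                                   amplitude = 50, baseline_s = 60,
                                   seed = 1, cfg = cf_config()) {
  elec <- make_electrodes(c("A", "B"), c("regA", "regB"),
                          xyz = rbind(c(0, 0, 0), c(40, 0, 0)))
  conns <- data.frame(from = c("A", "B"), to = c("B", "A"),
                      prob = c(p_ab, p_ba), stringsAsFactors = FALSE)
  conns <- conns[conns$prob > 0, , drop = FALSE]
  net <- make_network(elec, if (nrow(conns)) conns else NULL,
                      amplitude = amplitude)
  sched <- schedule_trials(c("A", "B"), n_trials, baseline_s = baseline_s,
                           seed = seed)
  rec <- simulate_session(net, sched, seed = seed + 1L)
  an <- analyze_session(rec, sched, cfg = cfg, seed = seed + 2L)
  cs <- an$connections[an$connections$state == "all", , drop = FALSE]
  est_ab <- cs$P[cs$stim == "A" & cs$chan == "B"]
  est_ba <- cs$P[cs$stim == "B" & cs$chan == "A"]
  data.frame(p_ab_true = p_ab, p_ba_true = p_ba,
             p_ab_est = est_ab, p_ba_est = est_ba,
             di_true = directionality_index(p_ab, p_ba),
             di_est = directionality_index(est_ab, est_ba),
             n_trials = n_trials)
}

#' Null-calibration experiment
#'
#' Simulates a session with an unconnected electrode pair (no true
#' responses anywhere), runs the detection chain, and returns the fraction
#' of single-trial tests declared significant - the empirical
#' false-positive rate of the surrogate-null test, nominally 5%.
#'
#' @param n_trials number of null stimulations.
#' @param baseline_s stimulation-free baseline (s).
#' @param seed integer seed.
#' @param cfg a [cf_config()].
#' @return list: `fp_rate`, `n_trials`, `trial_table`.
#' @export
null_calibration <- function(n_trials = 2000, baseline_s = 60, seed = 1,
                             cfg = cf_config()) {
  cfg$outlier_mode <- "flag"  # a null run has no artifact trials to drop
  elec <- make_electrodes(c("A", "B"), c("regA", "regB"),
                          xyz = rbind(c(0, 0, 0), c(40, 0, 0)))
  net <- make_network(elec, NULL)
  sched <- schedule_trials("A", n_trials, baseline_s = baseline_s,
                           seed = seed)
  rec <- simulate_session(net, sched, seed = seed + 1L)
  an <- analyze_session(rec, sched, cfg = cfg, seed = seed + 2L)
  tt <- an$trials[an$trials$stim_pair == "A" & an$trials$channel == "B", ]
  list(fp_rate = mean(tt$significant), n_trials = nrow(tt),
       trial_table = tt)
}

#' Simulate a sleep-modulation cohort
#'
#' Builds a synthetic multi-participant cohort for the sleep-modulation
#' analysis: each participant has one hippocampal and two neocortical
#' electrodes, fully connected with high-probability high-amplitude
#' connections; hippocampal efferences (hippocampus -> neocortex) carry an
#' NREM gain of `nrem_gain` (amplitude and probability multiplier), all
#' other connections are state-invariant. Each participant's session holds
#' one wake and one NREM (N2) block with `n_per_state` stimulations per
#' electrode each; the full pipeline is run per participant and the
#' connection x state metric rows are pooled.
#'
#' @param n_participants cohort size (default 13).
#' @param n_per_state stimulations per electrode per vigilance state.
#' @param nrem_gain NREM gain on hippocampal efferences (default 0.75,
#'   i.e. a -25% magnitude change).
#' @param amplitude evoked amplitude (default 80 = 8x background SD).
#' @param seed integer seed.
#' @param cfg a [cf_config()].
#' @return data.frame, one row per participant x connection x state
#'   (`W`/`NREM`), with `participant`, `connection`, `stim_region`,
#'   `resp_region`, `state`, `P`, `magnitude` - the input expected by
#'   [sleep_modulation()].
#' @export
simulate_sleep_cohort <- function(n_participants = 13, n_per_state = 8,
                                  nrem_gain = 0.75, amplitude = 80,
                                  seed = 1, cfg = cf_config()) {
  out <- list()
  for (p in seq_len(n_participants)) {
    sp <- seed + 1000L * p
    elec <- make_electrodes(c("HIP", "NC1", "NC2"),
                            c("hippocampus", "neocortex", "neocortex"),
                            xyz = rbind(c(0, 0, 0), c(40, 0, 0),
                                        c(0, 40, 10)))
    grid <- expand.grid(from = elec$name, to = elec$name,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, ]
    grid$gain_nrem <- ifelse(grid$from == "HIP" & grid$to != "HIP",
                             nrem_gain, 1)
    net <- make_network(elec, grid, prob = 0.95, amplitude = amplitude)
    s1 <- schedule_trials(elec$name, n_per_state, baseline_s = 60,
                          seed = sp)
    gap <- max(s1$onset_s) + 5
    s2 <- schedule_trials(elec$name, n_per_state, baseline_s = 0,
                          seed = sp + 1L)
    s2$onset_s <- s2$onset_s + gap
    s2$event_id <- s2$event_id + max(s1$event_id)
    s2$block_id <- 2L
    sched <- rbind(s1, s2)
    attr(sched, "baseline_windows") <- attr(s1, "baseline_windows")
    end_s <- max(sched$onset_s) + 3
    vig <- vigilance_track(data.frame(
      start_s = c(0, gap), end_s = c(gap, end_s + 1),
      state = c("W", "N2")))
    rec <- simulate_session(net, sched, vig, seed = sp + 2L)
    an <- analyze_session(rec, sched, vig, cfg = cfg, seed = sp + 3L)
    cs <- an$connections[an$connections$state %in% c("W", "NREM"), ,
                         drop = FALSE]
    if (is.null(cs) || !nrow(cs)) next
    reg <- function(e) elec$region[match(e, elec$name)]
    out[[p]] <- data.frame(
      participant = paste0("P", p),
      connection = paste0("P", p, ":", cs$stim, "->", cs$chan),
      stim_region = reg(cs$stim), resp_region = reg(cs$chan),
      state = cs$state, P = cs$P, magnitude = cs$magnitude,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
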