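# ---- session-level orchestration: detection -> connection metrics ----

# collapse a vigilance label to the analysis state group
.state_group <- function(state) {
  out <- rep(NA_character_, length(state))
  out[state == "W"] <- "W"
  out[state %in% c("N2", "N3")] <- "NREM"
  out[state == "R"] <- "REM"
  out  # N1 and unknown stay NA: excluded from state contrasts
}

#' Analyze a stimulation session
#'
#' End-to-end single-session analysis: preprocessing (unless the recording
#' is already at the analysis rate), epoching, per-connection single-trial
#' detection, and aggregation into the connection-level quantities. For
#' each directed electrode pair with at least `cfg$min_trials` mapping
#' trials it reports the effective-connection decision (FDR-corrected
#' across connections), signaling probability (pooled and per state),
#' latency, response magnitude, connection class, and - when
#' stimulation-response blocks are present - the excitability index per
#' state with its surrogate significance.
#'
#' Centroids and surrogate nulls are computed once per connection on the
#' pooled mapping trials; per-state probabilities then group the
#' trial-level decisions by the vigilance state at each stimulation.
#'
#' @param recording a `bipolar_recording` (raw or preprocessed).
#' @param events stimulation events data.frame.
#' @param vigilance a [vigilance_track()] or `NULL` (all wake).
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return list of class `session_analysis`: `connections` (one row per
#'   directed connection x state, states `all`/`W`/`NREM`/`REM`), `pairs`
#'   (one row per unordered pair x state with both directed probabilities
#'   and the directionality index), `exi` (per connection x state),
#'   `sr_curves` (per level), `trials` (per-trial score table), `config`.
#' @export
analyze_session <- function(recording, events, vigilance = NULL,
                            cfg = cf_config(), seed = 1) {
  if (recording$sampling_rate != cfg$target_rate_hz)
    recording <- preprocess_recording(recording, events, cfg)
  trials <- epoch_trials(recording, events, vigilance, cfg)
  meta <- trials$meta
  elec <- recording$channel_table
  dmat <- electrode_distances(elec)
  conn_rows <- list(); pair_rows <- list(); trial_rows <- list()
  exi_rows <- list(); sr_rows <- list()
  conn_keys <- unique(meta[meta$block_kind == "mapping",
                           c("stim_pair", "channel")])
  # baseline surrogate pools, one per recording channel
  pools <- list()
  need_n <- max(cfg$n_trial_surrogates,
                cfg$n_centroid_surrogates, cfg$n_exi_surrogates)
  for (ch in unique(conn_keys$channel)) {
    pools[[ch]] <- sample_baseline_epochs(
      recording, events, ch, 4 * need_n, cfg,
      seed = seed + match(ch, elec$name))
  }
  results <- list()
  for (i in seq_len(nrow(conn_keys))) {
    A <- conn_keys$stim_pair[i]; B <- conn_keys$channel[i]
    sel <- which(meta$stim_pair == A & meta$channel == B &
                   meta$block_kind == "mapping")
    if (length(sel) < cfg$min_trials) next
    sub <- list(meta = meta[sel, , drop = FALSE],
                pre = trials$pre[sel, , drop = FALSE],
                post = trials$post[sel, , drop = FALSE])
    det <- detect_connection(sub, pools[[B]], cfg,
                             seed = seed + 13L * i)
    results[[paste(A, B, sep = "->")]] <- det
    tt <- det$trial_table
    keep <- if (cfg$outlier_mode == "exclude") !tt$outlier else
      rep(TRUE, nrow(tt))
    groups <- .state_group(tt$state)
    dist_ab <- dmat[A, B]
    same_reg <- elec$region[match(A, elec$name)] ==
      elec$region[match(B, elec$name)]
    same_hem <- elec$hemisphere[match(A, elec$name)] ==
      elec$hemisphere[match(B, elec$name)]
    states <- c("all", "W", "NREM", "REM")
    for (st in states) {
      in_st <- if (st == "all") rep(TRUE, nrow(tt)) else
        !is.na(groups) & groups == st
      use <- keep & in_st
      if (!any(in_st)) next
      sp <- signaling_probability(tt$significant[use])
      sig_post <- sub$post[use & tt$significant, , drop = FALSE]
      mag <- response_magnitude(sig_post, cfg)
      conn_rows[[length(conn_rows) + 1]] <- data.frame(
        stim = A, chan = B, state = st,
        n_stims = sp$n_stims, n_significant = sp$n_significant, P = sp$P,
        latency_ms = as.numeric(det$latency_ms),
        magnitude = as.numeric(mag),
        effective = det$effective$significant,
        p_connection = det$effective$p_value,
        distance_mm = dist_ab, same_region = same_reg,
        same_hemisphere = same_hem, stringsAsFactors = FALSE)
    }
    trial_rows[[length(trial_rows) + 1]] <- tt
    # stimulation-response curves per state
    sr_sel <- which(meta$stim_pair == A & meta$channel == B &
                      meta$block_kind == "sr_curve")
    if (length(sr_sel) >= 2 * cfg$min_trials) {
      sr_meta <- meta[sr_sel, , drop = FALSE]
      sr_groups <- .state_group(sr_meta$state)
      wake_sel <- !is.na(sr_groups) & sr_groups == "W"
      wake_curve <- NULL; wake_max <- NULL
      for (st in c("W", "NREM", "REM")) {
        in_st <- !is.na(sr_groups) & sr_groups == st
        if (sum(in_st) < 2 * cfg$min_trials) next
        cv <- sr_curve(trials$post[sr_sel[in_st], , drop = FALSE],
                       sr_meta$intensity_ma[in_st], cfg)
        if (st == "W") {
          wake_curve <- cv
          cw <- cv[cv$complete, , drop = FALSE]
          wake_max <- if (nrow(cw)) max(cw$magnitude) else NULL
        }
        anchor <- if (!is.null(wake_max)) wake_max else NULL
        sur <- if (sum(cv$complete) >= 2 && !is.null(anchor))
          surrogate_exi(cv, pools[[B]], anchor, cfg = cfg,
                        seed = seed + 31L * i) else NULL
        ex <- excitability_index(cv, wake_max = anchor,
                                 surrogate_exis = sur, cfg = cfg)
        cv$stim <- A; cv$chan <- B; cv$state <- st
        sr_rows[[length(sr_rows) + 1]] <- cv
        exi_rows[[length(exi_rows) + 1]] <- data.frame(
          stim = A, chan = B, state = st, exi = as.numeric(ex$exi),
          exi_significant = as.logical(ex$significant),
          n_levels = ex$n_levels,
          wake_max = if (is.null(ex$wake_max)) NA_real_ else ex$wake_max,
          stringsAsFactors = FALSE)
      }
    }
  }
  connections <- if (length(conn_rows)) do.call(rbind, conn_rows) else NULL
  if (!is.null(connections)) {
    # FDR across connections (pooled rows carry the connection-level test)
    pooled <- connections$state == "all"
    padj <- p.adjust(connections$p_connection[pooled], method = "BH")
    key <- paste(connections$stim, connections$chan)
    adj_map <- stats::setNames(padj, key[pooled])
    connections$p_connection_fdr <- adj_map[key]
    connections$effective_fdr <-
      connections$p_connection_fdr <= cfg$fdr_alpha
    connections$class <- classify_connection(
      connections$distance_mm, connections$latency_ms,
      connections$same_region, connections$same_hemisphere, cfg)
  }
  pairs <- .pair_table(connections)
  structure(list(connections = connections, pairs = pairs,
                 exi = if (length(exi_rows)) do.call(rbind, exi_rows) else NULL,
                 sr_curves = if (length(sr_rows)) do.call(rbind, sr_rows) else NULL,
                 trials = if (length(trial_rows)) do.call(rbind, trial_rows) else NULL,
                 detections = results, config = cfg),
            class = "session_analysis")
}

# unordered-pair table with the directionality index per state
.pair_table <- function(connections) {
  if (is.null(connections)) return(NULL)
  rows <- list()
  for (st in unique(connections$state)) {
    cs <- connections[connections$state == st, , drop = FALSE]
    key <- t(apply(cs[, c("stim", "chan")], 1, sort))
    uk <- unique(data.frame(a = key[, 1], b = key[, 2],
                            stringsAsFactors = FALSE))
    for (j in seq_len(nrow(uk))) {
      A <- uk$a[j]; B <- uk$b[j]
      fwd <- cs[cs$stim == A & cs$chan == B, , drop = FALSE]
      rev <- cs[cs$stim == B & cs$chan == A, , drop = FALSE]
      p_ab <- if (nrow(fwd)) fwd$P[1] else NA_real_
      p_ba <- if (nrow(rev)) rev$P[1] else NA_real_
      di <- if (!is.na(p_ab) && !is.na(p_ba))
        directionality_index(p_ab, p_ba) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        a = A, b = B, state = st, P_AB = p_ab, P_BA = p_ba, DI_AB = di,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
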