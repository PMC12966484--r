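# ---- readers/writers ----
# Session layout (BIDS-iEEG-like, all text except the raw array):
#   signals.bin        float64 channels-major array (uncompressed)
#   signals.json       {n_channels, n_samples, sampling_rate_hz, channels}
#   electrodes.tsv     name region hemisphere x y z
#   events.tsv         onset_s stim_pair intensity_ma pulse_width_ms
#                      block_id block_kind event_id
#   vigilance.tsv      start_s end_s state
#   ground_truth.json  generator truth trial table (when available)
# Times in seconds from recording start, windows in ms, coordinates in mm,
# intensities in mA; unit suffixes are embedded in the column names.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a session to a directory
#'
#' @param dir output directory (created if needed).
#' @param recording a `bipolar_recording`.
#' @param events stimulation events data.frame.
#' @param vigilance a [vigilance_track()] or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, recording, events, vigilance = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- recording$signal
  con <- file(file.path(dir, "signals.bin"), "wb")
  writeBin(as.vector(t(sig)), con, size = 8)
  close(con)
  jsonlite::write_json(list(
    n_channels = nrow(sig), n_samples = ncol(sig),
    sampling_rate_hz = recording$sampling_rate,
    start_time_s = recording$start_time,
    channels = rownames(sig)),
    file.path(dir, "signals.json"), auto_unbox = TRUE, digits = NA)
  .write_tsv(recording$channel_table, file.path(dir, "electrodes.tsv"))
  ev <- events
  bw <- attr(events, "baseline_windows")
  .write_tsv(ev, file.path(dir, "events.tsv"))
  if (!is.null(bw)) .write_tsv(bw, file.path(dir, "baseline_windows.tsv"))
  if (!is.null(vigilance))
    .write_tsv(as.data.frame(vigilance), file.path(dir, "vigilance.tsv"))
  truth <- attr(recording, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         digits = NA, na = "null")
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return list: `recording`, `events`, `vigilance` (or `NULL`).
#' @export
read_session <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "signals.json"),
                             simplifyVector = TRUE)
  con <- file(file.path(dir, "signals.bin"), "rb")
  v <- readBin(con, "double", n = hdr$n_channels * hdr$n_samples, size = 8)
  close(con)
  sig <- matrix(v, nrow = hdr$n_channels, byrow = TRUE)
  rownames(sig) <- hdr$channels
  elec <- .read_tsv(file.path(dir, "electrodes.tsv"))
  events <- .read_tsv(file.path(dir, "events.tsv"))
  bwp <- file.path(dir, "baseline_windows.tsv")
  if (file.exists(bwp)) attr(events, "baseline_windows") <- .read_tsv(bwp)
  vig <- NULL
  vp <- file.path(dir, "vigilance.tsv")
  if (file.exists(vp)) vig <- vigilance_track(.read_tsv(vp))
  rec <- structure(list(signal = sig, sampling_rate = hdr$sampling_rate_hz,
                        channel_table = elec,
                        start_time = hdr$start_time_s),
                   class = "bipolar_recording")
  gtp <- file.path(dir, "ground_truth.json")
  if (file.exists(gtp))
    attr(rec, "truth") <- jsonlite::read_json(gtp, simplifyVector = TRUE)
  list(recording = rec, events = events, vigilance = vig)
}

#' Write session-analysis results
#'
#' Writes `connections.csv`, `pairs.csv`, `exi.csv`, `sr_curves.csv`,
#' `trials.csv` and a `metadata.json` echoing every analysis constant.
#'
#' @param analysis a `session_analysis` from [analyze_session()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(analysis$connections, "connections.csv")
  wr(analysis$pairs, "pairs.csv")
  wr(analysis$exi, "exi.csv")
  wr(analysis$sr_curves, "sr_curves.csv")
  wr(analysis$trials, "trials.csv")
  jsonlite::write_json(unclass(analysis$config),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
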