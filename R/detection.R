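# ---- single-trial response detection ----

#' Line length of a signal window
#'
#' The waveform-agnostic response-magnitude measure used throughout:
#' `LL = (sum_i |x_i - x_(i-1)| / N) * (sf / 1000)` with `N` the number of
#' samples in the window and `sf` the sampling frequency. Zero if and only
#' if the window is constant; homogeneous of degree one in the signal.
#'
#' @param x numeric vector (>= 2 samples) or a matrix (one window per row).
#' @param sampling_rate_hz sampling frequency `sf` in Hz.
#' @return nonnegative scalar (or vector, one per row).
#' @export
line_length <- function(x, sampling_rate_hz) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("window needs at least 2 samples", call. = FALSE)
    n <- ncol(x)
    return(rowSums(abs(x[, -1, drop = FALSE] - x[, -n, drop = FALSE])) / n *
             sampling_rate_hz / 1000)
  }
  if (length(x) < 2) stop("window needs at least 2 samples", call. = FALSE)
  sum(abs(diff(x))) / length(x) * sampling_rate_hz / 1000
}

# Pearson correlation of each row of X with vector y
.row_cors <- function(X, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(Xc^2))
  num <- as.vector(Xc %*% yc)
  out <- num / (sx * sy)
  out[!is.finite(out)] <- 0
  out
}

#' Two-centroid waveform clustering
#'
#' Partitions the post-stimulation analysis windows of a connection's
#' trials into two clusters by k-means on per-trial standardized waveforms
#' (for z-scored windows, squared Euclidean distance is proportional to the
#' correlation distance 1 - rho, so Lloyd iterations minimise the
#' correlation distance to the cluster means). Centroids are the plain
#' averages of the member trials' raw analysis windows. Deterministic under
#' a fixed seed; 10 random restarts.
#'
#' @param trials a `trial_set` (or a bare matrix of post-window epochs).
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return list of class `centroid_set`: `centroids` (2 x window matrix),
#'   `assignment`, `counts`, `degenerate` flag (fewer than 2 distinct
#'   waveforms, centroid duplicated).
#' @export
extract_centroids <- function(trials, cfg = cf_config(), seed = 1) {
  post <- if (is.list(trials) && !is.null(trials$post)) trials$post else
    trials
  W <- post[, .analysis_cols(cfg), drop = FALSE]
  n <- nrow(W)
  if (n < 1) stop("no trials", call. = FALSE)
  sds <- apply(W, 1, sd)
  Z <- (W - rowMeans(W)) / ifelse(sds == 0, 1, sds)
  Z[sds == 0, ] <- 0
  degenerate <- n < 2 || nrow(unique(Z)) < 2
  if (degenerate) {
    cen <- rbind(colMeans(W), colMeans(W))
    out <- list(centroids = cen, assignment = rep(1L, n),
                counts = c(n, 0L), degenerate = TRUE)
    class(out) <- "centroid_set"
    return(out)
  }
  km <- .with_seed(seed,
                   kmeans(Z, centers = 2, nstart = 10, iter.max = 50))
  cen <- rbind(colMeans(W[km$cluster == 1, , drop = FALSE]),
               colMeans(W[km$cluster == 2, , drop = FALSE]))
  out <- list(centroids = cen, assignment = km$cluster,
              counts = as.integer(table(factor(km$cluster, 1:2))),
              degenerate = FALSE)
  class(out) <- "centroid_set"
  out
}

#' Compound single-trial response score
#'
#' Scores one or more trials against a connection's centroids with the
#' compound metric `sign(rho) * rho^2 * LL`: the line length of the trial's
#' analysis window weighted by its squared Pearson correlation with the
#' best-matching centroid over lags up to +/-10 ms, keeping the sign of the
#' correlation at the maximising lag. `rho^2 -> 1` means the trial's energy
#' is fully attributable to the expected response waveform.
#'
#' @param post matrix of post-stimulation epochs (one row per trial) or a
#'   single epoch vector.
#' @param centroids a `centroid_set` from [extract_centroids()].
#' @param cfg a [cf_config()].
#' @return data.frame with columns `ll`, `rho`, `lag_ms`, `score`.
#'   Zero-variance trials score 0 and are flagged in `flat`.
#' @export
score_trial <- function(post, centroids, cfg = cf_config()) {
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  s <- .cfg_samples(cfg)
  cols <- .analysis_cols(cfg)
  lags <- -s$lag:s$lag
  n <- nrow(post)
  ll <- line_length(post[, cols, drop = FALSE], s$sf)
  best_r2 <- rep(-Inf, n)
  best_rho <- numeric(n)
  best_lag <- integer(n)
  for (k in 1:2) {
    cen <- centroids$centroids[k, ]
    if (sd(cen) == 0) next
    for (lg in lags) {
      idx <- cols + lg
      if (idx[1] < 1 || idx[length(idx)] > ncol(post)) next
      r <- .row_cors(post[, idx, drop = FALSE], cen)
      r2 <- r^2
      upd <- r2 > best_r2
      best_r2[upd] <- r2[upd]
      best_rho[upd] <- r[upd]
      best_lag[upd] <- lg
    }
  }
  flat <- apply(post[, cols, drop = FALSE], 1, sd) == 0 | !is.finite(best_r2)
  best_rho[flat] <- 0
  score <- sign(best_rho) * best_rho^2 * ll
  score[flat] <- 0
  data.frame(ll = ll, rho = best_rho, lag_ms = best_lag / s$sf * 1000,
             score = score, flat = flat)
}

#' Surrogate null distribution
#'
#' Builds the null distribution of a detection statistic from surrogate
#' epochs drawn from non-stimulated baseline data of the same channel,
#' computed identically to the real pipeline:
#' \describe{
#'   \item{`trial_score`}{each surrogate epoch is scored against the
#'     connection's centroids with [score_trial()]; `n` values (default
#'     400).}
#'   \item{`centroid_ll`}{for each centroid, `n` surrogate centroids are
#'     formed by averaging as many random baseline epochs as the centroid
#'     has member trials, and their line lengths pooled (2 x `n` values,
#'     default 2 x 200).}
#' }
#'
#' @param baseline_epochs matrix of baseline epochs (rows), post-window
#'   shaped, e.g. from [sample_baseline_epochs()].
#' @param statistic_kind `"trial_score"` or `"centroid_ll"`.
#' @param centroids `centroid_set`; required for both kinds (member counts
#'   for `centroid_ll`, reference waveforms for `trial_score`).
#' @param n surrogate count (per centroid for `centroid_ll`).
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return list of class `null_distribution`: sorted `values`, `n`,
#'   `statistic_kind`.
#' @export
build_null <- function(baseline_epochs, statistic_kind = c("trial_score",
                                                           "centroid_ll"),
                       centroids, n = NULL, cfg = cf_config(), seed = 1) {
  statistic_kind <- match.arg(statistic_kind)
  s <- .cfg_samples(cfg)
  cols <- .analysis_cols(cfg)
  m <- nrow(baseline_epochs)
  if (statistic_kind == "trial_score") {
    if (is.null(n)) n <- cfg$n_trial_surrogates
    # n distinct surrogate epochs whenever the pool allows
    idx <- .with_seed(seed, sample(m, n, replace = m < n))
    vals <- score_trial(baseline_epochs[idx, , drop = FALSE], centroids,
                        cfg)$score
    return(structure(list(values = sort(vals), n = length(vals),
                          statistic_kind = statistic_kind),
                     class = "null_distribution"))
  }
  if (is.null(n)) n <- cfg$n_centroid_surrogates
  counts <- pmax(1L, centroids$counts)
  per_centroid <- .with_seed(seed, {
    lapply(counts, function(mk) {
      sort(vapply(seq_len(n), function(i) {
        pick <- sample(m, mk, replace = TRUE)
        line_length(colMeans(baseline_epochs[pick, cols, drop = FALSE]),
                    s$sf)
      }, numeric(1)))
    })
  })
  structure(list(values = sort(unlist(per_centroid)), n = 2L * n,
                 statistic_kind = statistic_kind,
                 per_centroid = per_centroid, member_counts = counts),
            class = "null_distribution")
}

.null_threshold <- function(null, cfg) {
  quantile(null$values, cfg$percentile / 100, names = FALSE)
}

#' Test a connection for an effective response
#'
#' A connection is deemed effective when the line length of at least one
#' cluster centroid reaches the 95th percentile of its surrogate null.
#' Each centroid is compared against surrogate centroids averaging the same
#' number of baseline epochs as it has member trials, so the noise
#' suppression by averaging is matched. The p-value is the smaller of the
#' two per-centroid add-one estimates `(1 + #[null >= observed]) / (1 + n)`
#' (uncorrected; connection-level decisions are FDR-adjusted downstream).
#'
#' @param centroids a `centroid_set`.
#' @param null a `null_distribution` of kind `centroid_ll` built for the
#'   same centroid set (member counts must match).
#' @param cfg a [cf_config()].
#' @return list: `significant`, `p_value`, `observed_ll` (per centroid),
#'   `threshold` (per centroid), `latency_threshold` (threshold of the
#'   largest-membership centroid, used for latency detection on the
#'   all-trial average).
#' @export
test_effective_connection <- function(centroids, null, cfg = cf_config()) {
  if (null$statistic_kind != "centroid_ll")
    stop("null must be of kind centroid_ll", call. = FALSE)
  s <- .cfg_samples(cfg)
  obs <- line_length(centroids$centroids, s$sf)
  thr <- vapply(null$per_centroid, function(v)
    quantile(v, cfg$percentile / 100, names = FALSE), numeric(1))
  p_k <- vapply(seq_along(obs), function(k)
    (1 + sum(null$per_centroid[[k]] >= obs[k])) /
      (1 + length(null$per_centroid[[k]])), numeric(1))
  list(significant = any(obs >= thr), p_value = min(p_k),
       observed_ll = obs, threshold = thr,
       latency_threshold = thr[which.max(null$member_counts)])
}

#' Test a single trial score against the surrogate null
#'
#' One-sided: a trial is a significant response iff its compound score
#' reaches the 95th percentile of the trial-score surrogate null.
#'
#' @param score numeric vector of compound scores ([score_trial()]`$score`).
#' @param null a `null_distribution` of kind `trial_score`.
#' @param cfg a [cf_config()].
#' @return logical vector.
#' @export
test_single_trial <- function(score, null, cfg = cf_config()) {
  if (null$statistic_kind != "trial_score")
    stop("null must be of kind trial_score", call. = FALSE)
  score >= .null_threshold(null, cfg)
}

#' Flag artifactual high-line-length trials
#'
#' Trials whose line length exceeds `outlier_factor` (default 4) times the
#' connection-specific median line length are flagged; this automates the
#' visual screening of technical artifacts and epileptic discharges.
#'
#' @param ll numeric vector of per-trial line lengths for one connection.
#' @param cfg a [cf_config()].
#' @return logical vector of flags.
#' @export
flag_outliers <- function(ll, cfg = cf_config()) {
  if (length(ll) < cfg$min_trials) return(rep(FALSE, length(ll)))
  ll > cfg$outlier_factor * median(ll)
}

#' Signaling latency from an averaged response
#'
#' Latency to the first peak of the average cortical response: responses
#' are sought within the post-stimulation window as an elevation of line
#' length over a sliding analysis window (compared against the
#' connection-level surrogate threshold), and the latency is the time of
#' the first local extremum, with amplitude at least `prominence_sd`
#' baseline standard deviations, inside the elevated span. `NA` with a
#' reason attribute when no elevation or no qualifying peak is found.
#'
#' @param avg_post averaged post-stimulation epoch (post-window samples).
#' @param avg_pre averaged pre-stimulation epoch (used for the baseline SD
#'   and, when `ll_threshold` is `NULL`, for a fallback sliding-LL
#'   threshold).
#' @param cfg a [cf_config()].
#' @param ll_threshold line-length significance threshold, normally the
#'   95th percentile of the connection's centroid-level null.
#' @param prominence_sd peak amplitude threshold in baseline SDs.
#' @return latency in ms, or `NA` with `attr(, "reason")`.
#' @export
detect_latency <- function(avg_post, avg_pre, cfg = cf_config(),
                           ll_threshold = NULL, prominence_sd = 2) {
  s <- .cfg_samples(cfg)
  if (sd(avg_post) == 0) {
    return(structure(NA_real_, reason = "flat"))
  }
  starts <- (s$offset + 1):(length(avg_post) - s$ll + 1)
  sll <- vapply(starts, function(i)
    line_length(avg_post[i:(i + s$ll - 1)], s$sf), numeric(1))
  if (is.null(ll_threshold)) {
    pst <- seq_len(length(avg_pre) - s$ll + 1)
    pll <- vapply(pst, function(i)
      line_length(avg_pre[i:(i + s$ll - 1)], s$sf), numeric(1))
    ll_threshold <- quantile(pll, cfg$percentile / 100, names = FALSE)
  }
  elevated <- starts[sll >= ll_threshold]
  if (!length(elevated))
    return(structure(NA_real_, reason = "no_ll_elevation"))
  span <- elevated[1]:length(avg_post)
  base_sd <- sd(avg_pre)
  base_mean <- mean(avg_pre)
  d <- diff(avg_post)
  ext <- which(d[-length(d)] * d[-1] < 0) + 1   # sign change of slope
  ext <- ext[ext %in% span]
  ext <- ext[abs(avg_post[ext] - base_mean) >= prominence_sd * base_sd]
  if (!length(ext))
    return(structure(NA_real_, reason = "no_peak"))
  (ext[1] - 1) / s$sf * 1000
}

#' Detect responses on one connection
#'
#' Runs the whole single-trial detection chain for one directed connection
#' (stimulated electrode -> recording channel): centroid extraction, the
#' centroid-level surrogate test for an effective connection, the
#' trial-level compound-score test against a 400-surrogate null, outlier
#' flagging, and latency estimation from the averaged response.
#'
#' @param trials a `trial_set` restricted to this connection (or a list
#'   with `pre`/`post` matrices and `meta`).
#' @param baseline_epochs matrix of baseline epochs for the recording
#'   channel ([sample_baseline_epochs()]); the surrogate pool.
#' @param cfg a [cf_config()].
#' @param seed integer seed.
#' @return list of class `connection_detection`: `centroids`, `effective`
#'   (list from [test_effective_connection()]), `trial_table` (ll, rho,
#'   score, significant, outlier per trial), `latency_ms`, `null_trial`,
#'   `null_centroid`.
#' @export
detect_connection <- function(trials, baseline_epochs, cfg = cf_config(),
                              seed = 1) {
  post <- trials$post
  cent <- extract_centroids(trials, cfg, seed = seed)
  null_cent <- build_null(baseline_epochs, "centroid_ll", cent,
                          n = cfg$n_centroid_surrogates, cfg = cfg,
                          seed = seed + 1L)
  eff <- test_effective_connection(cent, null_cent, cfg)
  null_trial <- build_null(baseline_epochs, "trial_score", cent,
                           n = cfg$n_trial_surrogates, cfg = cfg,
                           seed = seed + 2L)
  sc <- score_trial(post, cent, cfg)
  sc$significant <- test_single_trial(sc$score, null_trial, cfg)
  sc$outlier <- flag_outliers(sc$ll, cfg)
  if (!is.null(trials$meta)) sc <- cbind(trials$meta, sc)
  keep <- if (cfg$outlier_mode == "exclude") !sc$outlier else
    rep(TRUE, nrow(sc))
  avg_post <- colMeans(post[keep, , drop = FALSE])
  avg_pre <- colMeans(trials$pre[keep, , drop = FALSE])
  lat <- if (sum(keep) >= cfg$min_trials)
    detect_latency(avg_post, avg_pre, cfg,
                   ll_threshold = eff$latency_threshold)
  else structure(NA_real_, reason = "too_few_trials")
  list(centroids = cent, effective = eff, trial_table = sc,
       latency_ms = lat, null_trial = null_trial,
       null_centroid = null_cent)
}
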