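# ---- group-level inference ----

#' Logistic model of signaling probability
#'
#' Fits `logit(P) = b0 + b1(Region_stim : Region_resp) + b2 * d`: a
#' binomial GLM on per-connection success counts (`n_significant` of
#' `n_stims`) with a combined stimulation-region x response-region factor
#' (cell coding, reference = first observed pair alphabetically) and
#' continuous inter-electrode distance in mm. Counts, not fractional
#' probabilities, carry the binomial weighting. Reports McFadden's
#' pseudo-R^2 against the intercept-only model; inestimable (unobserved or
#' separated) region-pair levels are listed in `dropped_levels`.
#'
#' @param table data.frame with columns `n_significant`, `n_stims`,
#'   `distance_mm`, `stim_region`, `resp_region`.
#' @return list of class `probability_model`: `fit` (the glm), `coefficients`
#'   (tidy data.frame), `pseudo_r2`, `n_observations`, `dropped_levels`.
#' @export
fit_probability_model <- function(table) {
  need <- c("n_significant", "n_stims", "distance_mm",
            "stim_region", "resp_region")
  stopifnot(all(need %in% names(table)))
  if (any(table$distance_mm <= 0))
    stop("distances must be positive", call. = FALSE)
  table$region_pair <- factor(paste(table$stim_region, table$resp_region,
                                    sep = ":"))
  fit <- glm(cbind(n_significant, n_stims - n_significant) ~
               region_pair + distance_mm,
             family = binomial(), data = table)
  null <- glm(cbind(n_significant, n_stims - n_significant) ~ 1,
              family = binomial(), data = table)
  pseudo_r2 <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null))
  cf <- summary(fit)$coefficients
  co <- data.frame(term = rownames(cf), estimate = cf[, 1],
                   std_error = cf[, 2], z = cf[, 3], p = cf[, 4],
                   row.names = NULL, stringsAsFactors = FALSE)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  structure(list(fit = fit, coefficients = co, pseudo_r2 = pseudo_r2,
                 n_observations = nrow(table), dropped_levels = dropped),
            class = "probability_model")
}

#' Participant-level directionality tests
#'
#' For each directed region pair, averages the two directed signaling
#' probabilities within participant, then tests their paired difference
#' across participants with a two-sided Wilcoxon signed-rank test,
#' Benjamini-Hochberg corrected across region pairs. Pairs observed in
#' fewer than `min_participants` participants are reported untested.
#'
#' @param di_table data.frame with columns `participant`, `stim_region`,
#'   `resp_region`, `P_AB` (stim->resp probability), `P_BA` (reverse).
#' @param min_participants minimal participants per pair (default 5).
#' @return data.frame (one row per region pair): participant count, mean
#'   within-participant DI, statistic, `p`, `p_fdr`, `tested`.
#' @export
participant_directionality <- function(di_table, min_participants = 5) {
  need <- c("participant", "stim_region", "resp_region", "P_AB", "P_BA")
  stopifnot(all(need %in% names(di_table)))
  key <- paste(di_table$stim_region, di_table$resp_region, sep = "->")
  rows <- lapply(unique(key), function(k) {
    sub <- di_table[key == k, , drop = FALSE]
    agg <- do.call(rbind, lapply(split(sub, sub$participant), function(p)
      data.frame(p_ab = mean(p$P_AB, na.rm = TRUE),
                 p_ba = mean(p$P_BA, na.rm = TRUE))))
    agg <- agg[complete.cases(agg), , drop = FALSE]
    n <- nrow(agg)
    di <- directionality_index(pmin(1, agg$p_ab), pmin(1, agg$p_ba))
    tested <- n >= min_participants
    if (tested && any(agg$p_ab != agg$p_ba)) {
      wt <- suppressWarnings(wilcox.test(agg$p_ab, agg$p_ba, paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    data.frame(region_pair = k, n_participants = n,
               mean_DI = mean(di, na.rm = TRUE), statistic = stat, p = p,
               tested = tested & !is.na(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out$p_fdr[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Connection-class contrasts
#'
#' Kruskal-Wallis tests of signaling probability and absolute
#' directionality across the connection classes (local, long-range
#' short-latency, long-range long-latency), with post-hoc pairwise
#' two-sided Mann-Whitney tests (BH-adjusted within each measure).
#'
#' @param metrics data.frame with columns `class`, `P` and optionally `DI`.
#' @return list: `tests` (Kruskal-Wallis rows), `posthoc` (pairwise rows),
#'   `notes` (e.g. omitted empty classes).
#' @export
class_contrasts <- function(metrics) {
  metrics <- metrics[!is.na(metrics$class) &
                       metrics$class != "unclassified", , drop = FALSE]
  classes <- unique(metrics$class)
  notes <- character()
  if (length(classes) < 2) {
    return(list(tests = NULL, posthoc = NULL,
                notes = "fewer than 2 populated classes; no test run"))
  }
  measures <- c(P = "P", DI = "DI")[c("P", "DI") %in% names(metrics)]
  tests <- list(); posthoc <- list()
  for (mname in names(measures)) {
    v <- metrics[[measures[[mname]]]]
    if (mname == "DI") v <- abs(v)
    ok <- !is.na(v)
    if (length(unique(metrics$class[ok])) < 2) {
      notes <- c(notes, paste0(mname, ": fewer than 2 classes with data"))
      next
    }
    kw <- kruskal.test(v[ok], factor(metrics$class[ok]))
    tests[[mname]] <- data.frame(
      measure = mname, statistic = unname(kw$statistic),
      df = unname(kw$parameter), p = kw$p.value, n = sum(ok),
      stringsAsFactors = FALSE)
    pw <- suppressWarnings(pairwise.wilcox.test(v[ok],
                                                factor(metrics$class[ok]),
                                                p.adjust.method = "BH"))
    pm <- as.data.frame(as.table(pw$p.value), stringsAsFactors = FALSE)
    pm <- pm[!is.na(pm$Freq), , drop = FALSE]
    if (nrow(pm))
      posthoc[[mname]] <- data.frame(measure = mname, group1 = pm$Var1,
                                     group2 = pm$Var2, p_fdr = pm$Freq,
                                     stringsAsFactors = FALSE)
  }
  list(tests = if (length(tests)) do.call(rbind, tests) else NULL,
       posthoc = if (length(posthoc)) do.call(rbind, posthoc) else NULL,
       notes = notes)
}

#' Sleep modulation of signaling
#'
#' Quantifies how sleep changes the connection-level quantities relative
#' to wake. Per region pair (participant level): the percent change in
#' response magnitude and excitability (`100 * (sleep - wake)/wake`,
#' state-complete connections only, averaged within participant) is tested
#' against zero with a two-sided Wilcoxon signed-rank test,
#' Benjamini-Hochberg corrected across region pairs within each measure.
#' Across connections: the Pearson correlation and Bland-Altman bias of
#' signaling probabilities between states, and a mixed-effects linear
#' model of the probability change with stimulation region as fixed and
#' participant as random effect (REML).
#'
#' @param table data.frame, one row per connection x state, with columns
#'   `participant`, `connection` (identifier), `stim_region`,
#'   `resp_region`, `state` (`"W"` plus sleep states), `P`, and optionally
#'   `magnitude`, `exi`.
#' @param sleep_state which sleep state to contrast with wake
#'   (default `"NREM"`).
#' @return list of class `sleep_modulation`: `contrasts` (per region pair
#'   x measure), `correlation`, `bland_altman` (bias and limits of
#'   agreement for P), `mixed_model` (coefficient table or `NULL` if the
#'   fit is not estimable), `n_state_complete`, `n_excluded`.
#' @export
sleep_modulation <- function(table, sleep_state = "NREM") {
  need <- c("participant", "connection", "stim_region", "resp_region",
            "state", "P")
  stopifnot(all(need %in% names(table)))
  w <- table[table$state == "W", , drop = FALSE]
  s <- table[table$state == sleep_state, , drop = FALSE]
  merged <- merge(w, s, by = c("participant", "connection", "stim_region",
                               "resp_region"),
                  suffixes = c("_w", "_s"))
  n_excluded <- length(unique(table$connection)) -
    length(unique(merged$connection))
  if (!nrow(merged)) stop("no state-complete connections", call. = FALSE)
  merged$dP <- merged$P_s - merged$P_w
  pct <- function(sleep, wake) 100 * (sleep - wake) / wake
  measures <- list()
  if ("magnitude_w" %in% names(merged))
    measures$magnitude <- pct(merged$magnitude_s, merged$magnitude_w)
  if ("exi_w" %in% names(merged))
    measures$exi <- pct(merged$exi_s, merged$exi_w)
  key <- paste(merged$stim_region, merged$resp_region, sep = "->")
  rows <- list()
  for (mname in names(measures)) {
    v <- measures[[mname]]
    for (k in unique(key)) {
      sub <- v[key == k]
      part <- merged$participant[key == k]
      agg <- tapply(sub, part, mean, na.rm = TRUE)
      agg <- agg[is.finite(agg)]
      if (length(agg) < 2 || all(agg == 0)) {
        rows[[length(rows) + 1]] <- data.frame(
          region_pair = k, measure = mname, n_participants = length(agg),
          mean_change_pct = mean(agg), p = NA_real_, tested = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      wt <- suppressWarnings(wilcox.test(agg, mu = 0))
      rows[[length(rows) + 1]] <- data.frame(
        region_pair = k, measure = mname, n_participants = length(agg),
        mean_change_pct = mean(agg), p = wt$p.value, tested = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(contrasts)) {
    contrasts$p_fdr <- NA_real_
    for (mname in unique(contrasts$measure)) {
      sel <- contrasts$measure == mname & contrasts$tested
      contrasts$p_fdr[sel] <- p.adjust(contrasts$p[sel], method = "BH")
    }
  }
  correlation <- if (nrow(merged) >= 3 && sd(merged$P_w) > 0 &&
                     sd(merged$P_s) > 0)
    cor(merged$P_w, merged$P_s) else NA_real_
  bias <- mean(merged$dP)
  loa <- bias + c(-1.96, 1.96) * sd(merged$dP)
  mixed <- NULL
  if (length(unique(merged$stim_region)) >= 2 &&
      length(unique(merged$participant)) >= 3) {
    fit <- try(suppressWarnings(
      suppressMessages(lmerTest::lmer(dP ~ stim_region + (1 | participant),
                                      data = merged, REML = TRUE))),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- suppressWarnings(summary(fit)$coefficients)
      mixed <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                          std_error = cf[, "Std. Error"],
                          p = cf[, "Pr(>|t|)"], row.names = NULL,
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(contrasts = contrasts, correlation = correlation,
                 bland_altman = list(bias = bias, loa = loa),
                 mixed_model = mixed,
                 n_state_complete = nrow(merged), n_excluded = n_excluded),
            class = "sleep_modulation")
}

#' Simulate a connection table from the logistic model
#'
#' Table-level generator for the probability model: connections get
#' distances and region pairs, true probabilities follow
#' `logit(P) = b0 + b1[pair] + b2 * d`, and significant-response counts are
#' binomial draws with `n_trials` stimulations each.
#'
#' @param n_connections number of connections.
#' @param beta0 intercept (log-odds).
#' @param beta2 distance coefficient (per mm).
#' @param pair_effects named numeric vector of region-pair log-odds offsets;
#'   names like `"A:B"`. Unlisted pairs get 0.
#' @param regions character vector of region labels to draw pairs from.
#' @param distance_range_mm range distances are drawn from (uniform).
#' @param n_trials stimulations per connection.
#' @param seed integer seed.
#' @return data.frame with the columns needed by [fit_probability_model()]
#'   plus `true_p`.
#' @export
simulate_connection_table <- function(n_connections = 200, beta0 = 0,
                                      beta2 = -0.05,
                                      pair_effects = NULL,
                                      regions = c("limbic", "frontal",
                                                  "temporal"),
                                      distance_range_mm = c(26, 90),
                                      n_trials = 200, seed = 1) {
  .with_seed(seed, {
    stim <- sample(regions, n_connections, replace = TRUE)
    resp <- sample(regions, n_connections, replace = TRUE)
    d <- runif(n_connections, distance_range_mm[1], distance_range_mm[2])
    eta <- beta0 + beta2 * d
    if (!is.null(pair_effects)) {
      key <- paste(stim, resp, sep = ":")
      eta <- eta + ifelse(key %in% names(pair_effects),
                          pair_effects[key], 0)
    }
    p <- plogis(eta)
    k <- rbinom(n_connections, n_trials, p)
    data.frame(stim_region = stim, resp_region = resp, distance_mm = d,
               n_stims = n_trials, n_significant = k, true_p = p,
               stringsAsFactors = FALSE)
  })
}
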