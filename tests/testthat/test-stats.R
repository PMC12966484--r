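test_that("Benjamini-Hochberg adjustment matches a hand-rolled step-up oracle", {
  # independent oracle: literal step-up rule on the sorted p-values
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    running <- Inf
    for (i in n:1) {
      running <- min(running, p[o[i]] * n / i)
      adj[o[i]] <- min(1, running)
    }
    adj
  }
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  expect_equal(p.adjust(p, method = "BH"), bh_oracle(p), tolerance = 1e-12)
  set.seed(41)
  p2 <- runif(50)
  expect_equal(p.adjust(p2, method = "BH"), bh_oracle(p2), tolerance = 1e-12)
})

test_that("the distance coefficient of the logistic model is recovered", {
  tab <- simulate_connection_table(n_connections = 200, beta0 = 0,
                                   beta2 = -0.05, n_trials = 200, seed = 42)
  fit <- fit_probability_model(tab)
  b2 <- fit$coefficients[fit$coefficients$term == "distance_mm", ]
  expect_lt(abs(b2$estimate - (-0.05)), 2 * b2$std_error)
  expect_gte(fit$pseudo_r2, 0)
  expect_lte(fit$pseudo_r2, 1)
})

test_that("a distance-free generator yields a CI covering zero", {
  tab <- simulate_connection_table(n_connections = 200, beta0 = -0.5,
                                   beta2 = 0, n_trials = 100, seed = 43)
  fit <- fit_probability_model(tab)
  b2 <- fit$coefficients[fit$coefficients$term == "distance_mm", ]
  expect_lt(abs(b2$estimate), 2 * b2$std_error)
})

test_that("a doubled region-pair log-odds shows up in its interaction term", {
  hits <- 0
  for (r in 1:10) {
    tab <- simulate_connection_table(
      n_connections = 300, beta0 = 0.5, beta2 = -0.02,
      pair_effects = c("limbic:frontal" = 1), n_trials = 100,
      seed = 400 + r)
    fit <- fit_probability_model(tab)
    co <- fit$coefficients
    row <- co[co$term == "region_pairlimbic:frontal", ]
    if (nrow(row) == 1 && row$estimate > 0 && row$p < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("participant-level directionality recovers a doubling as DI 0.5", {
  set.seed(44)
  rows <- list()
  for (p in 1:13) {
    for (c in 1:4) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, stim_region = "limbic", resp_region = "frontal",
        P_AB = rbinom(1, 200, 0.8) / 200, P_BA = rbinom(1, 200, 0.4) / 200)
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, stim_region = "frontal", resp_region = "temporal",
        P_AB = rbinom(1, 200, 0.6) / 200, P_BA = rbinom(1, 200, 0.6) / 200)
    }
  }
  out <- participant_directionality(do.call(rbind, rows))
  limbic <- out[out$region_pair == "limbic->frontal", ]
  expect_true(limbic$tested)
  expect_lt(limbic$p_fdr, 0.05)
  expect_gt(limbic$mean_DI, 0.4)
  expect_lt(limbic$mean_DI, 0.6)
  null_pair <- out[out$region_pair == "frontal->temporal", ]
  expect_gt(null_pair$p, 0.05)
})

test_that("single-participant pairs are reported untested", {
  one <- data.frame(participant = 1, stim_region = "a", resp_region = "b",
                    P_AB = 0.8, P_BA = 0.2)
  out <- participant_directionality(one)
  expect_false(out$tested)
  expect_true(is.na(out$p_fdr))
})

test_that("class contrasts separate shifted distributions and note degenerate input", {
  set.seed(45)
  mk <- function(n, p_mu, cls) data.frame(
    class = cls, P = pmin(1, pmax(0, rnorm(n, p_mu, 0.1))),
    DI = runif(n, -1, 1))
  tab <- rbind(mk(100, 0.9, "local"), mk(100, 0.6, "long_short"),
               mk(100, 0.2, "long_long"))
  res <- class_contrasts(tab)
  expect_lt(res$tests$p[res$tests$measure == "P"], 0.001)
  expect_equal(nrow(res$posthoc[res$posthoc$measure == "P", ]), 3)
  single <- class_contrasts(mk(50, 0.5, "local"))
  expect_null(single$tests)
  expect_match(single$notes, "fewer than 2")
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(46)
  ps <- replicate(200, {
    tab <- data.frame(class = rep(c("local", "long_short", "long_long"),
                                  each = 30),
                      P = runif(90))
    class_contrasts(tab)$tests$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical wake and sleep metrics give rho 1 and zero bias", {
  base <- data.frame(
    participant = rep(paste0("P", 1:6), each = 4),
    connection = paste0("c", 1:24),
    stim_region = rep(c("hippocampus", "neocortex"), 12),
    resp_region = rep(c("neocortex", "hippocampus"), 12),
    P = runif(24, 0.2, 0.9))
  base$magnitude <- runif(24, 0.5, 2)
  w <- transform(base, state = "W")
  s <- transform(base, state = "NREM")
  res <- sleep_modulation(rbind(w, s))
  expect_equal(res$correlation, 1)
  expect_equal(res$bland_altman$bias, 0)
  expect_true(all(res$contrasts$mean_change_pct == 0))
  expect_true(all(!res$contrasts$tested))
})

test_that("state-incomplete connections are excluded with counts", {
  set.seed(47)
  w <- data.frame(participant = "P1", connection = paste0("c", 1:6),
                  stim_region = "a", resp_region = "b", state = "W",
                  P = runif(6), magnitude = runif(6))
  s <- w[1:4, ]
  s$state <- "NREM"
  s$P <- s$P + 0.1
  res <- sleep_modulation(rbind(w, s))
  expect_equal(res$n_state_complete, 4)
  expect_equal(res$n_excluded, 2)
})
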