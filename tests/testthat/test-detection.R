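test_that("line length matches direct summation of the formula", {
  # independent oracle: literal sum of successive absolute differences
  ll_oracle <- function(x, sf) {
    acc <- 0
    for (i in 2:length(x)) acc <- acc + abs(x[i] - x[i - 1])
    acc / length(x) * sf / 1000
  }
  set.seed(10)
  for (i in 1:25) {
    n <- sample(10:300, 1)
    x <- rnorm(n)
    expect_equal(line_length(x, 500), ll_oracle(x, 500), tolerance = 1e-12)
  }
  # frozen worked case: alternating +/-1 over 125 samples at 500 Hz
  x <- rep(c(1, -1), length.out = 125)
  expect_equal(line_length(x, 500), 0.992, tolerance = 1e-12)
})

test_that("line length is zero iff constant and homogeneous of degree 1", {
  expect_equal(line_length(rep(4.2, 50), 500), 0)
  set.seed(11)
  x <- rnorm(100)
  expect_equal(line_length(3 * x, 500), 3 * line_length(x, 500))
  expect_error(line_length(1, 500), "2 samples")
  # matrix form agrees with the vector form row by row
  m <- rbind(x, 2 * x)
  expect_equal(line_length(m, 500),
               c(line_length(x, 500), line_length(2 * x, 500)),
               ignore_attr = TRUE)
})

test_that("two-polarity trials are recovered by the centroids", {
  cen <- extract_centroids(fx_polarity$post, seed = 1)
  tpl <- fx_polarity$template[.analysis_cols_test()]
  cors <- abs(c(cor(cen$centroids[1, ], tpl), cor(cen$centroids[2, ], tpl)))
  expect_true(all(cors > 0.9))
  # the two centroids face opposite directions
  expect_lt(cor(cen$centroids[1, ], cen$centroids[2, ]), -0.9)
  expect_equal(sum(cen$counts), nrow(fx_polarity$post))
  # sign-flipping every trial flips the centroid pair
  cen2 <- extract_centroids(-fx_polarity$post, seed = 1)
  flipped <- rbind(-cen2$centroids[1, ], -cen2$centroids[2, ])
  match1 <- max(cor(cen$centroids[1, ], flipped[1, ]),
                cor(cen$centroids[1, ], flipped[2, ]))
  expect_gt(match1, 0.99)
})

test_that("degenerate trial sets yield a duplicated, flagged centroid", {
  one <- matrix(rnorm(250), 1)
  cen <- extract_centroids(one, seed = 1)
  expect_true(cen$degenerate)
  expect_equal(cen$centroids[1, ], cen$centroids[2, ])
  same <- matrix(rep(rnorm(250), 5), 5, byrow = TRUE)
  cen <- extract_centroids(same, seed = 1)
  expect_true(cen$degenerate)
})

test_that("the compound score preserves sign and is bounded by line length", {
  cen <- extract_centroids(fx_polarity$post, seed = 1)
  cols <- .analysis_cols_test()
  trial <- rep(0, 250)
  trial[cols] <- cen$centroids[1, ]
  sc <- score_trial(trial, cen)
  expect_equal(sc$rho, 1, tolerance = 1e-9)
  expect_equal(sc$score, sc$ll, tolerance = 1e-9)
  sc_neg <- score_trial(-trial, cen)
  # the mirrored trial matches the opposite-polarity centroid positively,
  # so the compound score stays positive; against a single centroid it
  # would flip sign
  one_cen <- cen
  one_cen$centroids[2, ] <- cen$centroids[1, ]
  sc_neg1 <- score_trial(-trial, one_cen)
  expect_equal(sc_neg1$rho, -1, tolerance = 1e-9)
  expect_equal(sc_neg1$score, -sc_neg1$ll, tolerance = 1e-9)
  # dominance |score| <= LL on random trials
  set.seed(12)
  noise <- matrix(rnorm(20 * 250), 20)
  scn <- score_trial(noise, cen)
  expect_true(all(abs(scn$score) <= scn$ll + 1e-12))
  flat <- score_trial(rep(1, 250), cen)
  expect_true(flat$flat)
  expect_equal(flat$score, 0)
})

test_that("surrogate nulls honour their contracts", {
  ep <- sample_baseline_epochs(fx_pre, fx_schedule, "B", 800, seed = 20)
  cen <- extract_centroids(fx_polarity$post, seed = 1)
  null_t <- build_null(ep, "trial_score", cen, seed = 21)
  expect_equal(null_t$n, 400)
  expect_false(is.unsorted(null_t$values))
  # by definition of the 95th percentile, ~5% of the null exceeds it
  thr <- quantile(null_t$values, 0.95)
  expect_equal(mean(null_t$values > thr), 0.05, tolerance = 0.01)
  null_c <- build_null(ep, "centroid_ll", cen, n = 200, seed = 22)
  expect_equal(null_c$n, 400)   # 2 x 200, pooled over both centroids
  # determinism
  again <- build_null(ep, "trial_score", cen, seed = 21)
  expect_identical(null_t$values, again$values)
  expect_error(test_single_trial(1, null_c), "trial_score")
  expect_error(test_effective_connection(cen, null_t), "centroid_ll")
})

test_that("effective connections are declared against the centroid null", {
  ep <- sample_baseline_epochs(fx_pre, fx_schedule, "B", 800, seed = 23)
  # strong injected connection from the fixture session
  sel <- fx_trials$meta$stim_pair == "A" & fx_trials$meta$channel == "B"
  sub <- list(post = fx_trials$post[sel, , drop = FALSE],
              pre = fx_trials$pre[sel, , drop = FALSE])
  cen <- extract_centroids(sub$post, seed = 2)
  null_c <- build_null(ep, "centroid_ll", cen, seed = 24)
  res <- test_effective_connection(cen, null_c)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.01)
  # an observation below every null value is firmly non-significant
  tiny <- cen
  tiny$centroids <- tiny$centroids * 1e-6
  res0 <- test_effective_connection(tiny, null_c)
  expect_false(res0$significant)
  expect_gt(res0$p_value, 0.99)
})

test_that("high-SNR injected trials are detected at single-trial level", {
  det <- fx_analysis$detections[["A->B"]]
  tt <- det$trial_table
  truth_a <- fx_truth[fx_truth$stim_pair == "A", ]
  merged <- merge(tt, truth_a[, c("event_id", "injected")], by = "event_id")
  hit <- mean(merged$significant[merged$injected])
  expect_gt(hit, 0.95)
})

test_that("outlier flagging follows the 4x-median rule", {
  expect_equal(flag_outliers(rep(2, 20)), rep(FALSE, 20))
  ll <- c(rep(1, 19), 10)
  expect_equal(which(flag_outliers(ll)), 20L)
  expect_equal(flag_outliers(c(1, 9)), c(FALSE, FALSE))  # too few trials
})

test_that("latency lands on the first response peak", {
  sf <- 500
  t_s <- (0:249) / sf
  set.seed(13)
  pre <- rnorm(300, 0, 0.001)
  single <- evoked_template(t_s, latency_ms = 40, amplitude = 1, ratio = 0)
  lat <- detect_latency(single + rnorm(250, 0, 0.001), pre,
                        ll_threshold = 0.004)
  expect_equal(as.numeric(lat), 40, tolerance = 4)
  double <- -exp(-(t_s - 0.03)^2 / (2 * 0.008^2)) +
    0.8 * exp(-(t_s - 0.15)^2 / (2 * 0.02^2))
  lat2 <- detect_latency(double + rnorm(250, 0, 0.001), pre,
                         ll_threshold = 0.004)
  expect_equal(as.numeric(lat2), 30, tolerance = 4)
  flat <- detect_latency(rep(0, 250), pre)
  expect_true(is.na(flat))
})

test_that("noise-only averages rarely yield a latency", {
  set.seed(14)
  ep <- sample_baseline_epochs(fx_pre, fx_schedule, "B", 2000, seed = 25)
  cen <- extract_centroids(fx_polarity$post, seed = 1)
  null_c <- build_null(ep, "centroid_ll", cen, seed = 26)
  thr <- quantile(null_c$values, 0.95)
  nas <- vapply(1:20, function(i) {
    pick <- sample(nrow(ep), 40)
    avg <- colMeans(ep[pick, ])
    is.na(detect_latency(avg, rnorm(300, 0, sd(avg)), ll_threshold = thr))
  }, logical(1))
  expect_gte(sum(nas), 15)
})

test_that("fixture recovery: detected latency matches the injected latency", {
  det <- fx_analysis$detections[["A->B"]]
  expect_equal(as.numeric(det$latency_ms), 40, tolerance = 6)
})
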