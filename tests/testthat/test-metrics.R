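test_that("signaling probability is the significant fraction of stimulations", {
  expect_equal(signaling_probability(rep(c(TRUE, FALSE), each = 144))$P, 0.5)
  expect_equal(signaling_probability(rep(TRUE, 10))$P, 1)
  expect_true(is.na(signaling_probability(logical(0))$P))
})

test_that("directionality index reproduces its defining cases", {
  expect_equal(directionality_index(0.8, 0.4), 0.5)   # doubling <-> 0.5
  expect_equal(directionality_index(0.6, 0), 1)       # pure efference
  expect_equal(directionality_index(0, 0.6), -1)      # pure afference
  expect_equal(directionality_index(0.7, 0.7), 0)     # bidirectional
  expect_true(is.na(directionality_index(0, 0)))      # undefined, not 0
  expect_error(directionality_index(1.4, 0.2), "\\[0, 1\\]")
})

test_that("directionality is antisymmetric and bounded on a random grid", {
  set.seed(21)
  p1 <- runif(200)
  p2 <- runif(200)
  di <- directionality_index(p1, p2)
  expect_equal(di, -directionality_index(p2, p1))
  expect_true(all(abs(di) <= 1))
})

test_that("connections classify by distance, latency and region", {
  expect_equal(classify_connection(10, 30, TRUE, TRUE), "local")
  expect_equal(classify_connection(40, 30, FALSE, TRUE), "long_short")
  expect_equal(classify_connection(40, 120, FALSE, TRUE), "long_long")
  expect_equal(classify_connection(10, 30, FALSE, TRUE), "unclassified")
  expect_equal(classify_connection(10, 30, TRUE, FALSE), "unclassified")
  expect_equal(classify_connection(40, NA, FALSE, TRUE), "unclassified")
  expect_equal(classify_connection(c(10, 40), c(30, 70), c(TRUE, FALSE)),
               c("local", "long_long"))
})

test_that("excitability index hits its analytic anchors", {
  u <- (sr_intensities() - 0.2) / 11.8
  flat <- data.frame(norm_intensity = u, magnitude = 1, complete = TRUE)
  expect_equal(excitability_index(flat)$exi, 1)
  linear <- data.frame(norm_intensity = u, magnitude = u, complete = TRUE)
  expect_equal(excitability_index(linear)$exi, 0.5, tolerance = 1e-12)
  zero <- data.frame(norm_intensity = u, magnitude = 0, complete = TRUE)
  expect_equal(excitability_index(zero)$exi, 0)
})

test_that("incomplete stimulation-response levels are excluded", {
  u <- (sr_intensities() - 0.2) / 11.8
  curve <- data.frame(norm_intensity = u, magnitude = 1,
                      complete = c(TRUE, rep(FALSE, 12), TRUE))
  res <- excitability_index(curve)
  expect_equal(res$n_levels, 2)
  one <- curve
  one$complete <- c(TRUE, rep(FALSE, 13))
  expect_true(is.na(excitability_index(one)$exi))
  post <- matrix(rnorm(40 * 250), 40)
  int <- rep(c(0.2, 3, 6, 12), times = c(20, 14, 3, 3))
  cv <- sr_curve(post, int)
  expect_equal(cv$complete, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(cv$magnitude[!cv$complete])))
})

test_that("sleep-state curves reuse the wake normalisation anchor", {
  u <- (sr_intensities() - 0.2) / 11.8
  wake <- data.frame(norm_intensity = u, magnitude = 2 * u, complete = TRUE)
  anchor <- max(wake$magnitude)
  sleep <- data.frame(norm_intensity = u, magnitude = u, complete = TRUE)
  expect_equal(excitability_index(sleep, wake_max = anchor)$exi, 0.25,
               tolerance = 1e-12)
})

test_that("response magnitude needs five significant trials", {
  tpl <- fx_polarity$template
  five <- matrix(rep(tpl, 5), 5, byrow = TRUE)
  m5 <- response_magnitude(five)
  expect_equal(as.numeric(m5),
               line_length(tpl[.analysis_cols_test()], 500))
  four <- five[1:4, ]
  expect_true(is.na(response_magnitude(four)))
  expect_equal(attr(response_magnitude(four), "n"), 4)
  # averaging suppresses noise: 50 noisy copies stay within 10% of the
  # template's line length
  set.seed(22)
  noisy <- t(replicate(50, tpl + rnorm(250, 0, 0.3)))
  m50 <- response_magnitude(noisy)
  expect_equal(as.numeric(m50),
               line_length(tpl[.analysis_cols_test()], 500),
               tolerance = 0.1)
})

test_that("session analysis respects metric ranges and count identities", {
  cs <- fx_analysis$connections
  expect_true(all(cs$P >= 0 & cs$P <= 1))
  expect_true(all(cs$n_significant <= cs$n_stims))
  expect_equal(cs$P, cs$n_significant / cs$n_stims)
  pr <- fx_analysis$pairs
  expect_true(all(abs(pr$DI_AB[!is.na(pr$DI_AB)]) <= 1))
  tt <- fx_analysis$trials
  expect_true(all(abs(tt$score) <= tt$ll + 1e-12))
  # the strong direction dominates the fixture pair
  all_rows <- pr[pr$state == "all", ]
  expect_gt(all_rows$P_AB, all_rows$P_BA)
})
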