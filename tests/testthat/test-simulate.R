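test_that("identical seeds give bit-identical recordings", {
  sched <- schedule_trials(c("A", "B"), 3, baseline_s = 5, seed = 1)
  r1 <- simulate_session(fx_network, sched, seed = 42)
  r2 <- simulate_session(fx_network, sched, seed = 42)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_session(fx_network, sched, seed = 43)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("ground-truth trial table books every stimulation x connection", {
  n_a <- sum(fx_schedule$stim_pair == "A")
  n_b <- sum(fx_schedule$stim_pair == "B")
  expect_equal(nrow(fx_truth), n_a + n_b)
  # empirical injection rate converges on the generative probability
  inj_a <- fx_truth$injected[fx_truth$stim_pair == "A"]
  expect_lt(abs(mean(inj_a) - 0.9), 3 * sqrt(0.9 * 0.1 / n_a))
  expect_true(all(is.finite(fx_truth$latency_ms[fx_truth$injected])))
})

test_that("background spectrum falls with frequency and peaks at 50 Hz", {
  sched <- schedule_trials("A", 1, baseline_s = 30, seed = 5)
  rec <- simulate_session(fx_network, sched, seed = 6)
  x <- rec$signal["B", 1:(30 * 1024)]
  sp <- stats::spec.pgram(x, spans = 31, taper = 0, plot = FALSE)
  hz <- sp$freq * 1024
  band_power <- function(lo, hi) mean(sp$spec[hz >= lo & hz < hi])
  decades <- c(band_power(1, 4), band_power(4, 16), band_power(16, 45))
  expect_true(all(diff(log(decades)) < 0))
  line <- band_power(49, 51)
  neighbours <- mean(c(band_power(44, 48), band_power(52, 56)))
  expect_gt(line, 2 * neighbours)
})

test_that("schedules referencing unknown electrodes are rejected", {
  bad <- schedule_trials("Z", 2, baseline_s = 5, seed = 1)
  expect_error(simulate_session(fx_network, bad, seed = 1), "unknown")
})

test_that("network invariants are enforced", {
  el <- make_electrodes(c("A", "B"), c("r1", "r2"))
  expect_error(make_network(el, data.frame(from = "A", to = "A")), "self")
  expect_error(make_network(el, data.frame(from = "A", to = "B",
                                           prob = 1.2)), "\\[0, 1\\]")
  expect_error(make_network(el, data.frame(from = "A", to = "B",
                                           latency_ms = -5)), "positive")
  expect_error(make_network(el, data.frame(from = "A", to = "C")),
               "unknown")
  d <- electrode_distances(el)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("the evoked template has two opposite-polarity deflections", {
  t_s <- (0:409) / 1024
  w <- evoked_template(t_s, latency_ms = 40, amplitude = 2, ratio = 0.5)
  expect_equal(t_s[which.min(w)] * 1000, 40, tolerance = 2)
  expect_equal(t_s[which.max(w)] * 1000, 100, tolerance = 5)
  expect_equal(min(w), -2, tolerance = 0.05)
  expect_gt(max(w), 0.5)
})

test_that("incidence matrices are symmetric with planted contrast", {
  part <- setNames(rep(1:2, each = 4), paste0("a", 1:8))
  m <- make_incidence_matrix(part, 0.8, 0.1, seed = 3)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  within <- m[1:4, 1:4][upper.tri(m[1:4, 1:4])]
  between <- m[1:4, 5:8]
  expect_gt(mean(within), mean(between))
  expect_error(make_incidence_matrix(part, 1.2, 0.1), "\\[0, 1\\]")
})
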