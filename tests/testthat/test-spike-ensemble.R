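# Spike detection, scoring, PSTH and cross-correlation statistics.

test_that("the detector finds clean spikes at their peak samples", {
  x <- rep(0, 2000)
  peaks <- c(300, 900, 1500)
  for (p in peaks) x[p + (-2:2)] <- c(0.2, 0.6, 1, 0.6, 0.2)
  tr <- binned_trace(x, 1000, 10)
  det <- detect_spikes(tr, detector_params(window_samples = 101,
                                           sd_threshold = 4,
                                           min_amplitude = 0.01))
  expect_equal(det$n, 3)
  expect_equal(round(det$times * 1000) + 1, peaks)
  expect_error(detect_spikes(binned_trace(x[1:50], 1000, 10),
                             detector_params(window_samples = 101)),
               "window_samples")
})

test_that("pure noise yields no detections at a 10 SD threshold", {
  set.seed(2)
  tr <- binned_trace(rnorm(10000), 1000, 10)
  det <- detect_spikes(tr, detector_params(sd_threshold = 10))
  expect_equal(det$n, 0)
})

test_that("refractory pruning keeps the larger of close peaks", {
  x <- rep(0, 1000)
  x[500] <- 1; x[502] <- 2
  det <- detect_spikes(binned_trace(x, 1000, 1),
                       detector_params(window_samples = 101,
                                       sd_threshold = 1, min_amplitude = 0.1,
                                       refractory_ms = 4))
  expect_equal(det$n, 1)
  expect_equal(round(det$times * 1000) + 1, 502)
})

test_that("detection scoring matches greedy one-to-one matching", {
  truth <- spike_train(c(0.010, 0.020, 0.030), 0.1)
  det <- spike_train(c(0.0105, 0.0202, 0.045), 0.1)
  sc <- score_detection(det, truth, tolerance_ms = 2)
  expect_equal(c(sc$tp, sc$fn, sc$fp), c(2, 1, 1))
  expect_equal(sc$tp + sc$fn, truth$n)
  expect_equal(sc$tp + sc$fp, det$n)
  # identical trains
  sc2 <- score_detection(truth, truth, 2)
  expect_equal(c(sc2$tp, sc2$fp, sc2$fn), c(3, 0, 0))
  # empty detection
  sc3 <- score_detection(spike_train(numeric(0), 0.1), truth, 2)
  expect_equal(c(sc3$tp, sc3$fp, sc3$fn), c(0, 0, 3))
  # symmetry: swapping the trains swaps FP and FN
  sc4 <- score_detection(truth, det, 2)
  expect_equal(sc4$tp, sc$tp)
  expect_equal(sc4$fp, sc$fn)
  expect_equal(sc4$fn, sc$fp)
})

test_that("PSTH bins lags of target spikes around reference spikes", {
  a <- spike_train(c(0.1, 0.3, 0.5), 1)
  # self-PSTH: the zero-lag bin holds the self-coincidences
  p <- psth(a, a, window_s = 0.05, bin_s = 0.002)
  z <- which(abs(p$bin_center_s) < 1e-9)
  expect_equal(p$count[z], 3)
  # a +4 ms shift puts all mass in the bin centred at +4 ms
  b <- spike_train(a$times + 0.004, 1)
  p2 <- psth(a, b, window_s = 0.05, bin_s = 0.002)
  expect_equal(p2$count[abs(p2$bin_center_s - 0.004) < 1e-9], 3)
  expect_equal(sum(p2$count), 3)
  expect_error(psth(spike_train(numeric(0), 1), a), "empty")
  expect_error(psth(a, a, window_s = 0.05, bin_s = 0.003),
               "integer multiple")
})

test_that("PSTH conserves the number of in-window spike pairs", {
  r <- poisson_train(8, 10, seed = 31)
  t <- poisson_train(6, 10, seed = 32)
  p <- psth(r, t, window_s = 0.1, bin_s = 0.01)
  lags <- as.vector(outer(t$times, r$times, "-"))
  expect_equal(sum(p$count), sum(lags >= -0.05 & lags < 0.05))
})

test_that("independent Poisson trains match the rate-product expectation", {
  r <- poisson_train(5, 10, seed = 41)
  t <- poisson_train(5, 10, seed = 42)
  p <- psth(r, t, window_s = 0.05, bin_s = 0.002)
  expected <- r$n * t$n * 0.002 / 10
  # mean over the 25 bins, Poisson-ish error on the mean
  se <- sqrt(expected / nrow(p))
  expect_lt(abs(mean(p$count) - expected), 4 * se)
})

test_that("the shuffle null matches the closed-form rate product", {
  r <- poisson_train(6, 10, seed = 51)
  t <- poisson_train(7, 10, seed = 52)
  nb <- psth_null(r, t, window_s = 0.05, bin_s = 0.002, n_shuffles = 100,
                  seed = 9)
  expected <- r$n * t$n * 0.002 / 10
  expect_lt(abs(mean(nb$null_mean) - expected), 0.25 * expected)
  expect_true(all(nb$p5 <= nb$null_mean + 1e-9))
  expect_true(all(nb$null_mean <= nb$p95 + 1e-9))
  expect_warning(psth_null(r, t, n_shuffles = 10, seed = 1), "unstable")
})

test_that("synchronized bursting exceeds the PSTH null at zero lag", {
  m <- ensemble_model(n_cells = 2, duration_s = 10, burst_rate_Hz = 0.5,
                      sync_jitter_ms = 1, independent_rate_Hz = 1, seed = 5)
  sim <- simulate_ensemble(m, sample_rate = 1000)
  nb <- psth_null(sim[[1]]$spikes, sim[[2]]$spikes, 0.05, 0.002,
                  n_shuffles = 100, seed = 7)
  z <- which.min(abs(nb$bin_center_s))
  expect_gt(nb$observed[z], nb$p95[z])
})

test_that("normalized cross-correlation has unit zero-lag autocorrelation", {
  set.seed(61)
  x <- rnorm(500)
  cc <- subthreshold_xcorr(x, x, rate_Hz = 100)
  expect_equal(nrow(cc), 2 * 500 - 1)
  expect_equal(cc$value[cc$lag_s == 0], 1, tolerance = 1e-9)
  # y delayed by exactly 50 samples: peak at lag +50 samples
  y <- c(rep(0, 50), x[1:450])
  cc2 <- subthreshold_xcorr(x, y, rate_Hz = 100)
  expect_equal(cc2$lag_s[which.max(cc2$value)] * 100, 50)
  # independent white noise: |peak| < 4 / sqrt(n)
  z <- rnorm(1000); w <- rnorm(1000)
  cc3 <- subthreshold_xcorr(z, w, rate_Hz = 100)
  expect_lt(max(abs(cc3$value)), 4 / sqrt(1000))
})

test_that("epoch averaging and the cross-source null band behave", {
  set.seed(71)
  xs <- lapply(1:3, function(i) rnorm(300))
  ys <- lapply(1:3, function(i) rnorm(300))
  avg <- subthreshold_xcorr(xs, ys, rate_Hz = 100)
  single <- lapply(1:3, function(i)
    subthreshold_xcorr(xs[[i]], ys[[i]], rate_Hz = 100)$value)
  expect_equal(avg$value, (single[[1]] + single[[2]] + single[[3]]) / 3)
  bank <- lapply(1:6, function(i) rnorm(300))
  nb <- xcorr_null(bank, n_pairs = 100, seed = 3)
  expect_equal(attr(nb, "n_shuffles"), 100)
  z <- which.min(abs(nb$lag_s))
  expect_lt(abs(nb$null_mean[z]), 2 / sqrt(300))   # centred near 0
  expect_error(xcorr_null(bank[1:2], sources = c(1, 1)), "distinct sources")
})

test_that("spike trains round-trip through plain-text export", {
  s <- spike_train(c(0.01, 0.5, 0.93), 1, "cellA")
  path <- withr::local_tempfile(fileext = ".txt")
  write_spike_times(s, path)
  s2 <- read_spike_times(path, duration_s = 1, source = "cellA")
  expect_equal(s2$times, s$times)
})

test_that("the detector grid search ranks parameter sets by FP then TP", {
  x <- rep(0, 3000)
  peaks <- c(500, 1500, 2500)
  for (p in peaks) x[p + (-2:2)] <- c(0.2, 0.6, 1, 0.6, 0.2)
  set.seed(9)
  tr <- binned_trace(x + rnorm(3000, 0, 0.02), 1000, 10)
  truth <- spike_train((peaks - 1) / 1000, 3)
  tab <- tune_detector(tr, truth, window_samples = c(151, 301),
                       sd_threshold = c(4, 30), min_amplitude = 0.01)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$fp[1], 0)
  expect_equal(tab$tp[1], 3)     # best row recovers all spikes cleanly
  expect_true(all(diff(tab$fp) >= 0 | diff(tab$tp) <= 0))
})
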