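# ROI extraction, logarithmic correction, filtering, binning, detrending.

test_that("ROI traces sum binary values within the mask", {
  ones <- bit_plane_stack(array(1L, dim = c(4, 4, 6)), 9938.4)
  roi <- roi_mask(matrix(c(rep(TRUE, 10), rep(FALSE, 6)), 4, 4))
  tr <- extract_roi_trace(ones, roi)
  expect_equal(tr$counts, rep(10, 6))
  zeros <- bit_plane_stack(array(0L, dim = c(4, 4, 6)), 9938.4)
  expect_equal(extract_roi_trace(zeros, roi)$counts, rep(0, 6))
  big_roi <- roi_mask(matrix(TRUE, 6, 6))
  expect_error(extract_roi_trace(ones, big_roi), "outside")
})

test_that("ROI trace mean matches the binomial sum oracle", {
  lam <- 0.1; np <- 10000; m <- 100
  s <- constant_stack(lam, 10, 10, np, seed = 5)
  tr <- extract_roi_trace(s, roi_mask(matrix(TRUE, 10, 10)))
  p <- -expm1(-lam)                      # expected mean 100 * 0.09516
  se <- sqrt(m * p * (1 - p) / np)
  expect_lt(abs(mean(tr$counts) - m * p), 3 * se)
})

test_that("logarithmic trace correction inverts ROI occupancy", {
  tr <- photon_trace(c(0, 63, 2), 1000, 100)
  cor <- log_correct_trace(tr)
  expect_equal(cor$counts[1], 0)
  expect_equal(cor$counts[2], -100 * log(1 - 0.63))   # 99.43
  # low occupancy: ~1% correction
  expect_equal(cor$counts[3] / 2, -log(0.98) / 0.02, tolerance = 1e-9)
  expect_true(cor$corrected)
  expect_error(log_correct_trace(cor), "already corrected")
  # saturation maps to the documented cap
  sat <- log_correct_trace(photon_trace(c(100, 0), 1000, 100))
  expect_equal(sat$counts[1], -100 * log(1 / 200))
})

test_that("the zero-phase low-pass has unit DC gain and the designed rolloff", {
  const <- photon_trace(rep(7, 2000), 9938.4, 10)
  expect_lt(max(abs(lowpass(const, 2000)$counts - 7)), 1e-9)
  # 4 kHz tone at 10 kHz sampling, 2 kHz cutoff: >= 24 dB down
  tt <- (0:9999) / 10000
  x <- sin(2 * pi * 4000 * tt)
  f <- lowpass(photon_trace(x + 2, 10000, 10), 2000)
  resid <- f$counts[1000:9000] - 2
  expect_lt(max(abs(resid)), 10^(-24 / 20))
  expect_error(lowpass(const, 6000), "Nyquist")
})

test_that("a 10 Hz low-pass removes millisecond spikes", {
  rate <- 2000
  x <- rep(0, 4 * rate)
  for (t0 in c(1, 2, 3)) {                      # 2 ms rectangular spikes
    idx <- round(t0 * rate) + 0:3
    x[idx] <- 1
  }
  f <- lowpass(photon_trace(x + 1, rate, 10), 10)
  expect_lt(max(abs(f$counts - 1)), 0.1)
})

test_that("temporal binning averages non-overlapping groups", {
  tr <- photon_trace(c(0, 1, 0, 1), 1000, 5)
  b <- temporal_bin(tr, 2)
  expect_equal(b$values, c(0.5, 0.5))
  expect_equal(b$effective_rate_Hz, 500)
  b1 <- temporal_bin(tr, 1)
  expect_equal(b1$values, tr$counts)
  # remainder dropped; mean preserved over the kept samples
  tr2 <- photon_trace(1:10, 1000, 20)
  b3 <- temporal_bin(tr2, 3)
  expect_equal(length(b3$values), 3)
  expect_equal(mean(b3$values), mean(1:9))
  expect_error(temporal_bin(tr, 0), "bin_factor")
})

test_that("effective frame rates follow native rate / bin factor", {
  expect_equal(effective_frame_rate(10000, 10), 1000)
  expect_equal(effective_frame_rate(10000, 5), 2000)
  expect_equal(effective_frame_rate(10000, 20), 500)
  expect_equal(effective_frame_rate(123.4, 1), 123.4)
  expect_equal(bin_factor_for(9938.4, 100), 99L)
})

test_that("linear detrending removes exactly the OLS line", {
  t0 <- 0:999
  line <- 2 * t0 + 3
  expect_lt(max(abs(detrend_linear(line))), 1e-9)
  s <- sin(2 * pi * 7 * t0 / 1000)
  d1 <- detrend_linear(line + s)
  # oracle: the sinusoid minus its own OLS line (lm fit)
  fit <- lm(s ~ t0)
  oracle <- s - fitted(fit)
  expect_lt(sqrt(mean((d1 - oracle)^2)), 1e-9)
  # idempotence
  expect_lt(max(abs(detrend_linear(d1) - d1)), 1e-9)
  # zero mean and zero slope
  expect_lt(abs(mean(d1)), 1e-9)
  expect_lt(abs(coef(lm(d1 ~ t0))[2]), 1e-9)
})

test_that("spike-band isolation keeps transients and drops slow structure", {
  rate <- 9938.4
  n <- round(1.2 * rate)
  ramp <- seq(0, 10, length.out = n)
  tr_ramp <- photon_trace(ramp + 100, rate, 200)
  sb <- isolate_spike_band(tr_ramp)
  expect_equal(sb$effective_rate_Hz, rate / 10)
  expect_lt(max(abs(sb$values)), 0.01 * 10)     # < 1% of the ramp range
  # add 2 ms rectangular transients of amplitude 5
  x <- ramp + 100
  for (t0 in c(0.3, 0.6, 0.9)) {
    idx <- round(t0 * rate) + seq_len(round(0.002 * rate))
    x[idx] <- x[idx] + 5
  }
  sb2 <- isolate_spike_band(photon_trace(x, rate, 200))
  expect_gt(max(sb2$values), 0.8 * 5)
  # zero trace -> zero band
  sb0 <- isolate_spike_band(photon_trace(rep(0, n), rate, 200))
  expect_lt(max(abs(sb0$values)), 1e-9)
  # inversion makes negative-going spikes positive
  sb3 <- isolate_spike_band(photon_trace(200 - x, rate, 200), invert = TRUE)
  expect_gt(max(sb3$values), 0.8 * 5)
})

test_that("processing steps accumulate in the trace log", {
  s <- constant_stack(0.2, 6, 6, 500, seed = 2)
  tr <- extract_roi_trace(s, roi_mask(matrix(TRUE, 6, 6)))
  tr <- lowpass(log_correct_trace(tr), 2000)
  b <- temporal_bin(tr, 5)
  expect_match(b$log[1], "extract_roi_trace")
  expect_true(any(grepl("log_correct", b$log)))
  expect_true(any(grepl("lowpass\\(2000", b$log)))
  expect_match(b$log[length(b$log)], "temporal_bin\\(N=5\\)")
})

test_that("ROI masks round-trip through CSV and run-length JSON", {
  set.seed(11)
  m <- matrix(runif(48) < 0.4, 6, 8)
  m[3, ] <- TRUE
  roi <- roi_mask(m)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_roi_csv(roi, p1)
  expect_equal(read_roi_csv(p1)$mask, roi$mask)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_roi_json(roi, p2)
  expect_equal(read_roi_json(p2)$mask, roi$mask)
})
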