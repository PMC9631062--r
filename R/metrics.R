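# Step dF/F, SNR, F-V regression and time-constant fits.

#' Measurement windows for a step protocol
#'
#' Baseline is the first 100 ms; the per-step response windows lie 20--80 ms
#' inside each step of the standard protocols (steps at 100, 270, 440, 610
#' and 780 ms). In current clamp the middle (0 pA) step produces no
#' deflection and has no window, leaving 120--180, 290--350, 630--690 and
#' 800--860 ms; voltage clamp also uses 460--520 ms.
#'
#' @param baseline_ms `c(start, end)` of the baseline window in ms.
#' @param response_ms List of `c(start, end)` response windows in ms.
#' @return A `step_windows` object.
#' @export
step_windows <- function(baseline_ms = c(0, 100), response_ms) {
  if (!is.list(response_ms) || !length(response_ms))
    stop("`response_ms` must be a non-empty list of c(start, end)",
         call. = FALSE)
  all_w <- c(list(baseline_ms), response_ms)
  for (w in all_w)
    if (length(w) != 2 || w[2] <= w[1])
      stop("each window must be c(start, end) with end > start",
           call. = FALSE)
  starts <- vapply(all_w, `[`, 0, 1)
  ends <- vapply(all_w, `[`, 0, 2)
  o <- order(starts)
  if (any(starts[o][-1] < ends[o][-length(o)]))
    stop("windows must be non-overlapping", call. = FALSE)
  structure(list(baseline_ms = baseline_ms, response_ms = response_ms),
            class = "step_windows")
}

#' @rdname step_windows
#' @param mode `"current"` (4 windows) or `"voltage"` (5 windows).
#' @export
default_step_windows <- function(mode = c("current", "voltage")) {
  mode <- match.arg(mode)
  w <- list(c(120, 180), c(290, 350), c(460, 520), c(630, 690), c(800, 860))
  if (mode == "current") w <- w[-3]
  step_windows(response_ms = w)
}

# Half-open [start, end) window in ms -> 1-based sample indices at `rate`.
window_samples <- function(window_ms, rate, n, label = "window") {
  k_lo <- ceiling(window_ms[1] / 1000 * rate - 1e-9)
  k_hi <- ceiling(window_ms[2] / 1000 * rate - 1e-9) - 1
  if (k_hi + 1 > n || k_lo > k_hi)
    stop(sprintf("%s [%g, %g) ms exceeds the trace (%d samples at %.4g Hz)",
                 label, window_ms[1], window_ms[2], n, rate), call. = FALSE)
  (k_lo:k_hi) + 1L
}

#' Per-step dF/F and SNR of a subthreshold optical trace
#'
#' The mean over the baseline window is the baseline fluorescence F; for
#' each response window, `dF = mean(window) - F`, `dF/F = dF / F` and
#' `SNR = dF / sd(baseline)`. Windows are mapped to samples half-open
#' `[start, end)` at the trace's effective rate.
#'
#' @param trace A [binned_trace()] (typically 100 Hz).
#' @param windows A [step_windows()].
#' @param dv_mV Membrane-potential change paired with each response window
#'   (mV); optional.
#' @return A data frame with one row per response window: `dv_mV`, `dF`,
#'   `dff`, `snr`, plus attributes `F_baseline` and `sd_baseline`.
#' @export
step_metrics <- function(trace, windows, dv_mV = NULL) {
  stopifnot(inherits(trace, "binned_trace"), inherits(windows, "step_windows"))
  rate <- trace$effective_rate_Hz
  n <- length(trace$values)
  base_idx <- window_samples(windows$baseline_ms, rate, n, "baseline window")
  f0 <- mean(trace$values[base_idx])
  s0 <- sd(trace$values[base_idx])
  if (f0 == 0) stop("baseline fluorescence is zero", call. = FALSE)
  if (!is.null(dv_mV) && length(dv_mV) != length(windows$response_ms))
    stop("`dv_mV` must pair one value with each response window",
         call. = FALSE)
  res <- lapply(seq_along(windows$response_ms), function(i) {
    w <- windows$response_ms[[i]]
    idx <- window_samples(w, rate, n, sprintf("response window %d", i))
    dF <- mean(trace$values[idx]) - f0
    data.frame(window = i, start_ms = w[1], end_ms = w[2],
               dv_mV = if (is.null(dv_mV)) NA_real_ else dv_mV[i],
               dF = dF, dff = dF / f0, snr = dF / s0)
  })
  out <- do.call(rbind, res)
  attr(out, "F_baseline") <- f0
  attr(out, "sd_baseline") <- s0
  out
}

#' Membrane-potential change per window of an electrical trace
#'
#' Applies the same windowing as [step_metrics()] to a voltage trace:
#' per-window mean minus the baseline-window mean, in mV. Measuring dV this
#' way pairs optical and electrical readouts identically.
#'
#' @param v A [voltage_trace()].
#' @param windows A [step_windows()].
#' @return Numeric vector, one dV (mV) per response window.
#' @export
measure_dv <- function(v, windows) {
  stopifnot(inherits(v, "voltage_trace"), inherits(windows, "step_windows"))
  n <- length(v$values)
  base <- mean(v$values[window_samples(windows$baseline_ms, v$sample_rate, n,
                                       "baseline window")])
  vapply(seq_along(windows$response_ms), function(i) {
    idx <- window_samples(windows$response_ms[[i]], v$sample_rate, n,
                          sprintf("response window %d", i))
    mean(v$values[idx]) - base
  }, 0)
}

#' Linear regression through the origin
#'
#' Fits `y = slope * x` with the intercept fixed at (0, 0):
#' `slope = sum(x y) / sum(x^2)`; the coefficient of determination uses the
#' uncentred total sum of squares, `R^2 = 1 - sum((y - yhat)^2) / sum(y^2)`,
#' the standard convention for forced-origin regression.
#'
#' @param x,y Paired observations (e.g. dV in mV and dF/F), length >= 2.
#' @return A list with `slope`, `r_squared` and `n`.
#' @export
fv_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (all(x == 0)) stop("all x are zero; slope is undefined", call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  ssr <- sum((y - slope * x)^2)
  ssy <- sum(y^2)
  r2 <- if (ssy == 0) 1 else 1 - ssr / ssy
  list(slope = slope, r_squared = max(0, min(1, r2)), n = length(x))
}

#' Fit an exponential relaxation time constant
#'
#' Least-squares fit of `y(t) = A + B exp(-t / tau)` to the ~100 ms segment
#' following a step onset. Initialised from the endpoints (`A` = last
#' value, `B` = first - last, `tau` = time to 63% of the range); solved by
#' Levenberg-Marquardt with relative tolerance 1e-8 and at most 200
#' iterations. Non-convergence, a degenerate amplitude, or a tau outside
#' (0.1 ms, 1 s) yields a failure result with diagnostics rather than an
#' error.
#'
#' @param y Trace values over the fitted segment (>= 5 samples).
#' @param rate Sampling rate of the segment in Hz.
#' @return A list with `ok`, `tau_ms`, `asymptote` (A), `amplitude` (B),
#'   `rmse`, and `reason` when `ok` is `FALSE`.
#' @export
fit_tau <- function(y, rate) {
  check_scalar(rate, "rate")
  if (length(y) < 5)
    stop("segment must contain at least 5 samples", call. = FALSE)
  fail <- function(reason) list(ok = FALSE, tau_ms = NA_real_,
                                asymptote = NA_real_, amplitude = NA_real_,
                                rmse = NA_real_, reason = reason)
  rng <- range(y)
  if (diff(rng) == 0) return(fail("degenerate amplitude (constant segment)"))
  t_s <- (seq_along(y) - 1) / rate
  a0 <- y[length(y)]
  b0 <- y[1] - a0
  # time to reach 63% of the total excursion
  frac <- abs(y - y[1]) / max(abs(a0 - y[1]), .Machine$double.eps)
  k63 <- which(frac >= 0.632)[1]
  tau0 <- if (is.na(k63) || k63 <= 1) diff(range(t_s)) / 3 else t_s[k63]
  tau0 <- max(tau0, 1 / rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + B * exp(-t_s / tau),
                      start = list(A = a0, B = b0, tau = tau0),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  p <- coef(fit)
  tau_ms <- unname(p["tau"]) * 1000
  if (!is.finite(tau_ms) || tau_ms <= 0.1 || tau_ms >= 1000)
    return(fail(sprintf("tau %.3g ms outside (0.1 ms, 1 s)", tau_ms)))
  list(ok = TRUE, tau_ms = tau_ms, asymptote = unname(p["A"]),
       amplitude = unname(p["B"]),
       rmse = sqrt(mean(residuals(fit)^2)), reason = NULL)
}

#' Per-spike dF/F and SNR
#'
#' For each detected spike, `dF = peak intensity - F` where F is the mean of
#' the baseline values; `dF/F = dF / F` and `SNR = dF / sd(baseline)`. The
#' trace-level value is the mean over spikes.
#'
#' @param trace A [binned_trace()] of fluorescence intensity (positive-going
#'   spikes).
#' @param peak_idx Sample indices (1-based) of the detected spike peaks.
#' @param baseline Numeric vector of baseline samples of the same trace
#'   (e.g. the pre-stimulus 100 ms).
#' @return A list with `per_spike` (data frame: `peak_idx`, `dff`, `snr`)
#'   and trace-level `mean_dff`, `mean_snr`; empty `peak_idx` gives an empty
#'   result.
#' @export
spike_metrics <- function(trace, peak_idx, baseline) {
  stopifnot(inherits(trace, "binned_trace"))
  if (!length(peak_idx))
    return(list(per_spike = data.frame(peak_idx = integer(), dff = numeric(),
                                       snr = numeric()),
                mean_dff = NA_real_, mean_snr = NA_real_))
  if (any(peak_idx < 1 | peak_idx > length(trace$values)))
    stop("peak indices outside the trace", call. = FALSE)
  f0 <- mean(baseline)
  s0 <- sd(baseline)
  if (f0 == 0) stop("baseline mean is zero", call. = FALSE)
  dF <- trace$values[peak_idx] - f0
  per <- data.frame(peak_idx = peak_idx, dff = dF / f0, snr = dF / s0)
  list(per_spike = per, mean_dff = mean(per$dff), mean_snr = mean(per$snr))
}
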