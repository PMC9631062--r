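# ROI traces and the filtering / binning / detrending chain.

#' Photon-count trace at the native bit-plane rate
#'
#' @param counts Per-plane ROI-summed counts.
#' @param frame_rate_Hz Native bit-plane rate.
#' @param n_pixels Number of ROI pixels (M).
#' @param corrected Has the logarithmic response been corrected?
#' @param log Character vector of processing steps applied so far.
#' @return A `photon_trace`.
#' @export
photon_trace <- function(counts, frame_rate_Hz, n_pixels,
                         corrected = FALSE, log = character()) {
  check_scalar(frame_rate_Hz, "frame_rate_Hz")
  check_scalar(n_pixels, "n_pixels", integer = TRUE)
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(counts = counts, frame_rate_Hz = frame_rate_Hz,
                 n_pixels = as.integer(n_pixels), corrected = corrected,
                 log = log),
            class = "photon_trace")
}

#' Trace after temporal binning
#'
#' @param values Binned values.
#' @param effective_rate_Hz Effective sampling rate (native rate divided by
#'   the cumulative bin factor).
#' @param bin_factor Cumulative bin factor N.
#' @param log Character vector of processing steps.
#' @return A `binned_trace`.
#' @export
binned_trace <- function(values, effective_rate_Hz, bin_factor,
                         log = character()) {
  check_scalar(effective_rate_Hz, "effective_rate_Hz")
  structure(list(values = as.numeric(values),
                 effective_rate_Hz = effective_rate_Hz,
                 bin_factor = as.integer(bin_factor), log = log),
            class = "binned_trace")
}

trace_rate <- function(x) {
  if (inherits(x, "photon_trace")) x$frame_rate_Hz
  else if (inherits(x, "binned_trace")) x$effective_rate_Hz
  else stop("not a trace object", call. = FALSE)
}

trace_field <- function(x) if (inherits(x, "photon_trace")) "counts" else "values"

#' Extract the ROI-summed photon trace from a bit-plane stack
#'
#' For each bit plane, binary values are summed within the ROI; the per-plane
#' sums concatenated over time form the optical trace at the native rate.
#'
#' @param stack A [bit_plane_stack()].
#' @param roi An [roi_mask()] with the same frame dimensions.
#' @return A [photon_trace()].
#' @export
extract_roi_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "bit_plane_stack"), inherits(roi, "roi_mask"))
  if (roi$height != stack$height || roi$width != stack$width) {
    bad <- which(roi$mask, arr.ind = TRUE)
    bad <- bad[bad[, 1] > stack$height | bad[, 2] > stack$width, ,
               drop = FALSE]
    stop(sprintf(
      "ROI raster (%d x %d) does not match the stack frame (%d x %d); %d member pixels fall outside",
      roi$height, roi$width, stack$height, stack$width, nrow(bad)),
      call. = FALSE)
  }
  planes <- stack$planes
  dim(planes) <- c(stack$height * stack$width, stack$n_planes)
  counts <- colSums(planes[as.vector(roi$mask), , drop = FALSE])
  photon_trace(counts, stack$frame_rate_Hz, roi$n_pixels,
               log = sprintf("extract_roi_trace(M=%d)", roi$n_pixels))
}

#' Correct the logarithmic pixel response of an ROI trace
#'
#' Treats the per-plane ROI occupancy `counts / M` as the saturating binary
#' response of M identical pixels and inverts it:
#' `counts' = -M * ln(1 - counts / M)`. Full occupancy (`counts = M`) is
#' capped at `-M * ln(1 / (2 M))`.
#'
#' @param trace An uncorrected [photon_trace()].
#' @return A [photon_trace()] with `corrected = TRUE`.
#' @export
log_correct_trace <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  if (trace$corrected) stop("trace is already corrected", call. = FALSE)
  m <- trace$n_pixels
  if (m == 0L) stop("ROI has zero pixels", call. = FALSE)
  if (any(trace$counts > m))
    stop("counts exceed the ROI pixel count", call. = FALSE)
  p <- pmin(trace$counts / m, 1 - 1 / (2 * m))
  photon_trace(-m * log1p(-p), trace$frame_rate_Hz, m, corrected = TRUE,
               log = c(trace$log, "log_correct_trace"))
}

# Steady-state initial conditions for a step input (scipy lfilter_zi).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  compT <- matrix(0, n - 1, n - 1)     # companion(a) transposed
  compT[, 1] <- -a[2:n]
  if (n > 2) compT[cbind(1:(n - 2), 2:(n - 1))] <- 1
  solve(diag(n - 1) - compT, b[2:n] - a[2:n] * b[1])
}

# Zero-phase forward-backward IIR filtering with odd reflection padding and
# steady-state initial conditions, so a constant input is returned exactly.
filtfilt_zi <- function(x, b, a) {
  n <- length(x)
  # pad long enough for the slowest pole's transient to die out (matters
  # for cutoffs far below the sampling rate, e.g. the 10 Hz stage)
  r_max <- max(Mod(polyroot(rev(a / a[1]))))
  settle <- if (r_max < 1) ceiling(8 / (1 - r_max)) else n - 1
  padlen <- min(n - 1, max(3 * max(length(a), length(b)), settle))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .iir_df2t(b, a, ext, zi * ext[1])
  y <- rev(.iir_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so spike
#' timing is preserved); DC gain is exactly 1.
#'
#' @param trace A [photon_trace()] or [binned_trace()].
#' @param cutoff_Hz Cutoff frequency; must be below the Nyquist frequency of
#'   the trace.
#' @param order Filter order per pass.
#' @return A trace of the same class, length preserved.
#' @export
lowpass <- function(trace, cutoff_Hz, order = 4) {
  rate <- trace_rate(trace)
  if (cutoff_Hz >= rate / 2)
    stop(sprintf("cutoff %.6g Hz is not below the Nyquist frequency %.6g Hz",
                 cutoff_Hz, rate / 2), call. = FALSE)
  if (cutoff_Hz <= 0) stop("cutoff must be > 0", call. = FALSE)
  fl <- signal::butter(order, cutoff_Hz / (rate / 2), "low")
  f <- trace_field(trace)
  trace[[f]] <- filtfilt_zi(trace[[f]], fl$b, fl$a)
  if (inherits(trace, "photon_trace")) trace[[f]] <- pmax(trace[[f]], 0)
  trace$log <- c(trace$log, sprintf("lowpass(%g Hz, order %d, zero-phase)",
                                    cutoff_Hz, order))
  trace
}

#' Temporal binning by averaging consecutive samples
#'
#' Non-overlapping means of `bin_factor` consecutive samples; a trailing
#' remainder shorter than one bin is dropped. The effective rate is the
#' source rate divided by `bin_factor`.
#'
#' @param trace A [photon_trace()] or [binned_trace()].
#' @param bin_factor Integer N >= 1.
#' @return A [binned_trace()]; cumulative bin factors multiply when the
#'   input is already binned.
#' @export
temporal_bin <- function(trace, bin_factor) {
  check_scalar(bin_factor, "bin_factor", integer = TRUE)
  if (bin_factor < 1) stop("`bin_factor` must be >= 1", call. = FALSE)
  n <- as.integer(bin_factor)
  f <- trace_field(trace)
  x <- trace[[f]]
  nb <- length(x) %/% n
  if (nb < 1) stop("trace shorter than one bin", call. = FALSE)
  vals <- if (n == 1) x else colMeans(matrix(x[seq_len(nb * n)], nrow = n))
  prev_n <- if (inherits(trace, "binned_trace")) trace$bin_factor else 1L
  binned_trace(vals, effective_rate_Hz = trace_rate(trace) / n,
               bin_factor = prev_n * n,
               log = c(trace$log, sprintf("temporal_bin(N=%d)", n)))
}

#' Effective frame rate after binning
#'
#' @param native_Hz Native bit-plane rate.
#' @param bin_factor Number of consecutive planes averaged.
#' @return `native_Hz / bin_factor`.
#' @examples
#' effective_frame_rate(10000, 10)  # 1 kHz
#' @export
effective_frame_rate <- function(native_Hz, bin_factor) {
  check_scalar(native_Hz, "native_Hz")
  check_scalar(bin_factor, "bin_factor", integer = TRUE)
  if (bin_factor < 1) stop("`bin_factor` must be >= 1", call. = FALSE)
  native_Hz / bin_factor
}

#' Bin factor that reaches a target effective rate
#'
#' @param native_Hz Native rate.
#' @param target_Hz Desired effective rate.
#' @return `round(native_Hz / target_Hz)`, at least 1.
#' @export
bin_factor_for <- function(native_Hz, target_Hz) {
  max(1L, as.integer(round(native_Hz / target_Hz)))
}

#' Remove a linear baseline trend
#'
#' Subtracts the ordinary least-squares straight line; the output has zero
#' mean and zero linear trend, and the operation is idempotent.
#'
#' @param trace A [binned_trace()], [photon_trace()] or bare numeric vector.
#' @return Same type as the input.
#' @export
detrend_linear <- function(trace) {
  if (is.numeric(trace)) return(detrend_vec(trace))
  f <- trace_field(trace)
  trace[[f]] <- detrend_vec(trace[[f]])
  trace$log <- c(trace$log, "detrend_linear")
  trace
}

detrend_vec <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to detrend", call. = FALSE)
  t0 <- seq_len(n) - (n + 1) / 2           # centred time axis
  x - mean(x) - t0 * sum(t0 * x) / sum(t0^2)
}

#' Isolate the spike band of a native-rate trace
#'
#' Removes subthreshold events and baseline drift by subtracting a 10 Hz
#' zero-phase low-pass copy from the (already 2 kHz low-passed) trace, then
#' bins to a 1 kHz effective rate. With `mode = "direct"` the 10 Hz low-pass
#' output itself is binned instead (the literal second-low-pass reading).
#'
#' @param trace A [photon_trace()] at the native rate.
#' @param lowcut_Hz Cutoff of the slow (subthreshold) component.
#' @param target_rate_Hz Effective rate after binning.
#' @param mode `"subtract"` (default) or `"direct"`.
#' @param invert Multiply by -1 so that spikes from a negatively coupled
#'   indicator become positive-going.
#' @return A [binned_trace()].
#' @export
isolate_spike_band <- function(trace, lowcut_Hz = 10, target_rate_Hz = 1000,
                               mode = c("subtract", "direct"),
                               invert = FALSE) {
  stopifnot(inherits(trace, "photon_trace"))
  mode <- match.arg(mode)
  slow <- filtfilt_zi(trace$counts,
                      signal::butter(4, lowcut_Hz / (trace$frame_rate_Hz / 2),
                                     "low")$b,
                      signal::butter(4, lowcut_Hz / (trace$frame_rate_Hz / 2),
                                     "low")$a)
  band <- if (mode == "subtract") trace$counts - slow else slow
  if (invert) band <- -band
  # the band is signed, so it is carried in a binned_trace, not a
  # photon_trace (whose counts must be non-negative)
  nb <- bin_factor_for(trace$frame_rate_Hz, target_rate_Hz)
  nbin <- length(band) %/% nb
  vals <- colMeans(matrix(band[seq_len(nbin * nb)], nrow = nb))
  binned_trace(vals, effective_rate_Hz = trace$frame_rate_Hz / nb,
               bin_factor = nb,
               log = c(trace$log,
                       sprintf("isolate_spike_band(%s, %g Hz%s)", mode,
                               lowcut_Hz, if (invert) ", inverted" else ""),
                       sprintf("temporal_bin(N=%d)", nb)))
}
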