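# Spike trains, detection and ground-truth scoring.

#' Spike train
#'
#' Ordered spike times for one cell.
#'
#' @param times Spike times in seconds, within `[0, duration_s)`.
#' @param duration_s Recording length in seconds.
#' @param source Identifier of the source cell/trace.
#' @return A `spike_train`.
#' @export
spike_train <- function(times, duration_s, source = "") {
  check_scalar(duration_s, "duration_s")
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration_s))
    stop("spike times must lie in [0, duration_s)", call. = FALSE)
  structure(list(times = times, duration_s = duration_s, source = source,
                 n = length(times)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s%s\n", x$n, x$duration_s,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Write / read spike times as plain text (one per line, seconds)
#'
#' @param spikes A [spike_train()].
#' @param path Output path.
#' @param duration_s Recording duration (read only).
#' @param source Source id (read only).
#' @return `path` (write) or a [spike_train()] (read).
#' @export
write_spike_times <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  writeLines(formatC(spikes$times, format = "g", digits = 15), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path, duration_s, source = "") {
  x <- scan(path, what = double(), quiet = TRUE)
  spike_train(sort(x), duration_s, source)
}

#' Spike-detector parameters
#'
#' Three free parameters control the detector (plus a refractory gap):
#' rolling-window size for the local baseline/noise estimate, a threshold in
#' multiples of the local noise SD, and an absolute amplitude floor.
#'
#' @param window_samples Rolling-window size in samples (odd; even values
#'   are rounded up).
#' @param sd_threshold Peak threshold as a multiple of the local noise SD.
#' @param min_amplitude Absolute spike-band amplitude floor.
#' @param refractory_ms Minimum inter-peak gap in ms; of two closer peaks
#'   the larger is kept.
#' @return A `detector_params` object.
#' @export
detector_params <- function(window_samples = 301, sd_threshold = 4,
                            min_amplitude = 1e-12, refractory_ms = 4) {
  check_scalar(window_samples, "window_samples", integer = TRUE)
  check_scalar(sd_threshold, "sd_threshold")
  check_scalar(min_amplitude, "min_amplitude")
  check_scalar(refractory_ms, "refractory_ms")
  w <- as.integer(window_samples)
  if (w %% 2L == 0L) w <- w + 1L
  structure(list(window_samples = w, sd_threshold = sd_threshold,
                 min_amplitude = min_amplitude, refractory_ms = refractory_ms),
            class = "detector_params")
}

#' Detect spikes in a spike-band trace
#'
#' The local baseline is a rolling median over `window_samples`; the local
#' noise SD is `1.4826 * rolling median(|x - rolling median|)` (a rolling
#' MAD, robust to the spikes themselves). Candidate spikes are local maxima
#' whose deviation from the rolling median exceeds both
#' `sd_threshold * noise` and `min_amplitude`; peaks closer than the
#' refractory gap keep the larger.
#'
#' @param spike_band A [binned_trace()] with positive-going spikes
#'   (typically the 1 kHz spike band).
#' @param params A [detector_params()].
#' @return A [spike_train()] of peak times (peak sample / effective rate).
#' @export
detect_spikes <- function(spike_band, params = detector_params()) {
  stopifnot(inherits(spike_band, "binned_trace"),
            inherits(params, "detector_params"))
  x <- spike_band$values
  n <- length(x)
  if (params$window_samples >= n)
    stop("`window_samples` must be smaller than the trace length",
         call. = FALSE)
  base <- runmed(x, params$window_samples, endrule = "median")
  dev <- x - base
  noise <- 1.4826 * runmed(abs(dev), params$window_samples,
                           endrule = "median")
  is_max <- c(FALSE, dev[2:(n - 1)] >= dev[1:(n - 2)] &
                     dev[2:(n - 1)] > dev[3:n], FALSE)
  cand <- which(is_max & dev > params$sd_threshold * noise &
                  dev > params$min_amplitude)
  # refractory pruning: keep the larger of any pair closer than the gap
  if (length(cand) > 1) {
    gap <- params$refractory_ms / 1000 * spike_band$effective_rate_Hz
    keep <- logical(length(cand))
    ord <- order(dev[cand], decreasing = TRUE)
    taken <- numeric(0)
    for (i in ord) {
      if (!length(taken) || min(abs(taken - cand[i])) >= gap) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  spike_train((cand - 1) / spike_band$effective_rate_Hz,
              duration_s = n / spike_band$effective_rate_Hz,
              source = "detected")
}

#' Score detected spikes against ground truth
#'
#' Greedy nearest-first one-to-one matching within a time tolerance:
#' candidate (detected, truth) pairs are taken in order of increasing
#' |offset|; each spike matches at most once. Unmatched detected spikes are
#' false positives, unmatched truth spikes false negatives.
#'
#' @param detected,truth [spike_train()] objects over the same recording.
#' @param tolerance_ms Matching tolerance (+/- ms).
#' @return A `detection_score`: counts `tp`, `fp`, `fn`, the matched-pair
#'   data frame (`truth_s`, `detected_s`, `offset_ms`) and `tolerance_ms`.
#' @export
score_detection <- function(detected, truth, tolerance_ms = 2) {
  stopifnot(inherits(detected, "spike_train"), inherits(truth, "spike_train"))
  tol <- tolerance_ms / 1000
  pairs <- NULL
  if (detected$n && truth$n) {
    d <- outer(truth$times, detected$times, function(a, b) abs(a - b))
    idx <- which(d <= tol, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(d[idx]), , drop = FALSE]
      used_t <- logical(truth$n); used_d <- logical(detected$n)
      sel <- logical(nrow(idx))
      for (i in seq_len(nrow(idx))) {
        ti <- idx[i, 1]; di <- idx[i, 2]
        if (!used_t[ti] && !used_d[di]) {
          sel[i] <- TRUE; used_t[ti] <- TRUE; used_d[di] <- TRUE
        }
      }
      m <- idx[sel, , drop = FALSE]
      pairs <- data.frame(
        truth_s = truth$times[m[, 1]],
        detected_s = detected$times[m[, 2]],
        offset_ms = (detected$times[m[, 2]] - truth$times[m[, 1]]) * 1000)
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(tp = tp, fp = detected$n - tp, fn = truth$n - tp,
                 pairs = pairs, tolerance_ms = tolerance_ms),
            class = "detection_score")
}

#' Grid-search detector parameters against ground truth
#'
#' Scores every combination of the supplied parameter grids against a
#' ground-truth train and returns them ranked by the tuning objective:
#' minimal false positives first, then maximal true positives. A
#' convenience for calibrating against simultaneous electrophysiology;
#' analysis defaults are deliberately not derived from it.
#'
#' @param spike_band A [binned_trace()] spike-band trace.
#' @param truth Ground-truth [spike_train()].
#' @param window_samples,sd_threshold,min_amplitude Vectors of candidate
#'   values.
#' @param refractory_ms Refractory gap (fixed).
#' @param tolerance_ms Matching tolerance for scoring.
#' @return Data frame of all combinations with `tp`, `fp`, `fn`, sorted
#'   best first.
#' @export
tune_detector <- function(spike_band, truth,
                          window_samples = c(151, 301, 501),
                          sd_threshold = c(3, 4, 5, 6),
                          min_amplitude = 1e-12,
                          refractory_ms = 4, tolerance_ms = 2) {
  grid <- expand.grid(window_samples = window_samples,
                      sd_threshold = sd_threshold,
                      min_amplitude = min_amplitude)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- detector_params(grid$window_samples[i], grid$sd_threshold[i],
                         grid$min_amplitude[i], refractory_ms)
    sc <- tryCatch(score_detection(detect_spikes(spike_band, p), truth,
                                   tolerance_ms),
                   error = function(e) NULL)
    if (is.null(sc)) return(NULL)
    cbind(grid[i, , drop = FALSE],
          data.frame(tp = sc$tp, fp = sc$fp, fn = sc$fn))
  })
  out <- do.call(rbind, res)
  out[order(out$fp, -out$tp), , drop = FALSE]
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("<detection_score> TP %d, FP %d, FN %d (tolerance +/- %g ms)\n",
              x$tp, x$fp, x$fn, x$tolerance_ms))
  invisible(x)
}
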