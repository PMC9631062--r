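# Ensemble synchrony statistics: PSTH and subthreshold cross-correlation
# with shuffle-derived null bands.

#' Peristimulus time histogram between two spike trains
#'
#' For each reference spike, target spikes with lag in
#' `[-window_s/2, +window_s/2)` are assigned to half-open bins of width
#' `bin_s` centred on zero lag; counts are summed over all reference
#' spikes. Millisecond-level correlation uses a 50 ms window with 2 ms
#' bins; second-level correlation a 1 s window with 100 ms bins.
#'
#' @param reference,target [spike_train()] objects. Using the same train
#'   for both counts the zero-lag self-coincidences.
#' @param window_s Total lag window (s); must be an integer multiple of
#'   `bin_s`.
#' @param bin_s Bin width (s).
#' @return A data frame with `bin_center_s` and `count`, class `psth`.
#' @export
psth <- function(reference, target, window_s = 0.05, bin_s = 0.002) {
  stopifnot(inherits(reference, "spike_train"), inherits(target, "spike_train"))
  if (reference$n == 0) stop("reference train is empty", call. = FALSE)
  nb <- window_s / bin_s
  if (abs(nb - round(nb)) > 1e-9)
    stop("`window_s` must be an integer multiple of `bin_s`", call. = FALSE)
  nb <- as.integer(round(nb))
  edges <- seq(-window_s / 2, window_s / 2, by = bin_s)
  counts <- integer(nb)
  if (target$n > 0) {
    lags <- as.vector(outer(target$times, reference$times, "-"))
    lags <- lags[lags >= -window_s / 2 & lags < window_s / 2]
    if (length(lags)) {
      bin <- findInterval(lags, edges, rightmost.closed = FALSE)
      tab <- tabulate(bin, nbins = nb)
      counts <- tab
    }
  }
  structure(data.frame(bin_center_s = edges[-length(edges)] + bin_s / 2,
                       count = counts),
            class = c("psth", "data.frame"),
            window_s = window_s, bin_s = bin_s,
            n_reference = reference$n, n_target = target$n)
}

# Uniform redraw of spike times preserving the count (default shuffle), or
# ISI shuffling preserving the inter-spike-interval multiset.
shuffle_train <- function(train, scheme = c("uniform", "isi")) {
  scheme <- match.arg(scheme)
  if (train$n == 0) return(train)
  times <- switch(scheme,
    uniform = sort(runif(train$n, 0, train$duration_s)),
    isi = {
      isi <- diff(c(0, train$times))
      cumsum(sample(isi))
    })
  times <- times[times < train$duration_s]
  # runif/sample ties are measure-zero; nudge any that collide
  if (any(diff(times) <= 0))
    times <- sort(times + runif(length(times), 0, 1e-9))
  spike_train(times, train$duration_s, train$source)
}

#' PSTH with a shuffle-derived null band
#'
#' Recomputes the PSTH after randomly shuffling the spike times of both
#' trains (uniform redraw over the recording, counts preserved; optionally
#' ISI shuffling). The band is the per-bin mean and 5--95% percentile
#' envelope over the shuffles; observed bins outside the band indicate
#' temporal structure beyond firing rate.
#'
#' @inheritParams psth
#' @param n_shuffles Number of shuffled pairs (default 100); fewer than 20
#'   triggers a warning (unstable percentiles).
#' @param seed Integer seed for the shuffles.
#' @param scheme Shuffle scheme, `"uniform"` (default) or `"isi"`.
#' @return A data frame (class `null_band`) with `bin_center_s`, `observed`,
#'   `null_mean`, `p5`, `p95`; attribute `n_shuffles`.
#' @export
psth_null <- function(reference, target, window_s = 0.05, bin_s = 0.002,
                      n_shuffles = 100, seed = 1L,
                      scheme = c("uniform", "isi")) {
  scheme <- match.arg(scheme)
  if (n_shuffles < 20)
    warning("fewer than 20 shuffles: percentile band is unstable",
            call. = FALSE)
  obs <- psth(reference, target, window_s, bin_s)
  set.seed(as.integer(seed))
  sh <- vapply(seq_len(n_shuffles), function(i) {
    psth(shuffle_train(reference, scheme), shuffle_train(target, scheme),
         window_s, bin_s)$count
  }, numeric(nrow(obs)))
  band(obs$bin_center_s, "bin_center_s", obs$count, sh, n_shuffles)
}

band <- function(axis, axis_name, observed, draws, n_draws) {
  out <- data.frame(axis = axis, observed = observed,
                    null_mean = rowMeans(draws),
                    p5 = apply(draws, 1, quantile, 0.05),
                    p95 = apply(draws, 1, quantile, 0.95))
  names(out)[1] <- axis_name
  structure(out, class = c("null_band", "data.frame"), n_shuffles = n_draws)
}

xcorr_values <- function(x) {
  if (inherits(x, "binned_trace")) x$values
  else if (inherits(x, "photon_trace")) x$counts
  else as.numeric(x)
}

#' Normalized cross-correlation of subthreshold traces
#'
#' Each trace is z-scored and the full-lag cross-correlation computed with
#' the biased (divisor n) estimator, so that the autocorrelation of a trace
#' with itself is exactly 1 at zero lag. When lists of equal-length epochs
#' are supplied, per-epoch curves are averaged.
#'
#' @param x,y [binned_trace()] objects (typically 100 Hz, detrended),
#'   numeric vectors, or lists of such epochs.
#' @param rate_Hz Sampling rate used for the lag axis; taken from `x` when
#'   it is a trace.
#' @return A data frame with `lag_s` and `value` over all lags
#'   `-(n-1) .. (n-1)`.
#' @export
subthreshold_xcorr <- function(x, y, rate_Hz = NULL) {
  xs <- if (is.list(x) && !inherits(x, c("binned_trace", "photon_trace")))
    x else list(x)
  ys <- if (is.list(y) && !inherits(y, c("binned_trace", "photon_trace")))
    y else list(y)
  if (length(xs) != length(ys))
    stop("x and y must have the same number of epochs", call. = FALSE)
  if (is.null(rate_Hz))
    rate_Hz <- tryCatch(trace_rate(xs[[1]]), error = function(e) 1)
  curves <- lapply(seq_along(xs), function(i) {
    a <- xcorr_values(xs[[i]]); b <- xcorr_values(ys[[i]])
    if (length(a) != length(b))
      stop(sprintf("epoch %d: trace lengths differ (%d vs %d)", i,
                   length(a), length(b)), call. = FALSE)
    n <- length(a)
    cc <- ccf(a, b, lag.max = n - 1, plot = FALSE, demean = TRUE)
    # ccf at positive lag k correlates x[t+k] with y[t]; flip the axis so
    # that a positive lag means y is delayed relative to x
    lag <- -as.vector(cc$lag) / rate_Hz
    ord <- order(lag)
    data.frame(lag_s = lag[ord], value = as.vector(cc$acf)[ord])
  })
  out <- curves[[1]]
  if (length(curves) > 1) {
    for (k in 2:length(curves)) out$value <- out$value + curves[[k]]$value
    out$value <- out$value / length(curves)
  }
  out
}

#' Cross-cell null band for subthreshold correlation
#'
#' Builds the null distribution of the normalized cross-correlation by
#' randomly pairing traces from *different* sources (cells/slices), the
#' surrogate for cell pairs that share firing statistics but no common
#' drive.
#'
#' @param bank List of traces ([binned_trace()] or numeric), all the same
#'   length.
#' @param sources Source identifier per bank entry; pairs are drawn across
#'   distinct sources only. Defaults to one source per entry.
#' @param n_pairs Number of random pairings (default 100).
#' @param seed Integer seed.
#' @param observed Optional observed cross-correlation curve (output of
#'   [subthreshold_xcorr()]) to embed in the result; otherwise the observed
#'   column is NA.
#' @return A data frame (class `null_band`) with `lag_s`, `observed`,
#'   `null_mean`, `p5`, `p95`.
#' @export
xcorr_null <- function(bank, sources = seq_along(bank), n_pairs = 100,
                       seed = 1L, observed = NULL) {
  if (length(bank) < 2 || length(unique(sources)) < 2)
    stop("need traces from at least 2 distinct sources", call. = FALSE)
  if (length(sources) != length(bank))
    stop("`sources` must label every bank entry", call. = FALSE)
  lens <- vapply(bank, function(b) length(xcorr_values(b)), 0L)
  if (length(unique(lens)) != 1)
    stop("all bank traces must have the same length", call. = FALSE)
  rate <- tryCatch(trace_rate(bank[[1]]), error = function(e) 1)
  set.seed(as.integer(seed))
  draws <- NULL
  lag_s <- NULL
  for (k in seq_len(n_pairs)) {
    repeat {
      ij <- sample(length(bank), 2)
      if (sources[ij[1]] != sources[ij[2]]) break
    }
    cur <- subthreshold_xcorr(bank[[ij[1]]], bank[[ij[2]]], rate_Hz = rate)
    if (is.null(draws)) {
      draws <- matrix(0, nrow(cur), n_pairs)
      lag_s <- cur$lag_s
    }
    draws[, k] <- cur$value
  }
  obs_vals <- if (is.null(observed)) rep(NA_real_, length(lag_s))
              else observed$value
  band(lag_s, "lag_s", obs_vals, draws, n_pairs)
}

#' Write a null-band result as CSV
#'
#' @param x A `null_band` data frame from [psth_null()] or [xcorr_null()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_band_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
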