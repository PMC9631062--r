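#' Simulate the passive membrane response to a step protocol
#'
#' In current clamp each step relaxes exponentially from the present
#' potential toward `resting + I * R` with the membrane time constant. In
#' voltage clamp the command potential is followed with a fixed 1 ms settling
#' constant (clean command steps). Between steps (when the protocol has a
#' non-zero `inter_step_s`) the membrane relaxes back to rest/holding.
#'
#' @param protocol A [step_protocol()].
#' @param cell A [cell_model()].
#' @param sample_rate Sampling rate in Hz (>= 1 kHz).
#' @param tail_s Relaxation back to rest appended after the last step (s);
#'   lets a full post-onset analysis window fit inside the trace.
#' @return A [voltage_trace()] with attributes `step_onsets_s` (onset time of
#'   each step) and `steady_dV_mV` (steady-state deflection of each step,
#'   mV). Total duration is `baseline_s + n steps * step_duration_s +
#'   (n - 1) * inter_step_s + tail_s`.
#' @export
simulate_step_response <- function(protocol, cell, sample_rate = 20000,
                                   tail_s = 0.05) {
  stopifnot(inherits(protocol, "step_protocol"), inherits(cell, "cell_model"))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("`sample_rate` must be a positive number", call. = FALSE)
  if (sample_rate < 1000)
    stop("`sample_rate` must be >= 1 kHz to resolve step kinetics",
         call. = FALSE)

  rest <- if (protocol$mode == "voltage") protocol$holding_mV else
    cell$resting_mV
  tau_s <- if (protocol$mode == "voltage") 1e-3 else
    cell$tau_membrane_ms / 1000

  steady_dV <- if (protocol$mode == "current")
    protocol$step_levels * cell$resistance_MOhm * 1e-3
  else
    protocol$step_levels - protocol$holding_mV

  # Build the segment list: baseline, then (step, gap) per level.
  seg_target <- rest
  seg_dur <- protocol$baseline_s
  onsets <- numeric(0)
  t_cursor <- protocol$baseline_s
  for (i in seq_along(protocol$step_levels)) {
    onsets <- c(onsets, t_cursor)
    seg_target <- c(seg_target, rest + steady_dV[i])
    seg_dur <- c(seg_dur, protocol$step_duration_s)
    t_cursor <- t_cursor + protocol$step_duration_s
    if (protocol$inter_step_s > 0 && i < length(protocol$step_levels)) {
      seg_target <- c(seg_target, rest)
      seg_dur <- c(seg_dur, protocol$inter_step_s)
      t_cursor <- t_cursor + protocol$inter_step_s
    }
  }
  if (tail_s > 0) {
    seg_target <- c(seg_target, rest)
    seg_dur <- c(seg_dur, tail_s)
  }
  total_s <- sum(seg_dur)
  n <- round(total_s * sample_rate)
  values <- numeric(n)
  v0 <- rest
  seg_start <- cumsum(c(0, seg_dur))
  for (s in seq_along(seg_dur)) {
    k_lo <- ceiling(seg_start[s] * sample_rate - 1e-6)
    k_hi <- min(n - 1, ceiling(seg_start[s + 1] * sample_rate - 1e-6) - 1)
    if (k_hi < k_lo) next
    tt <- (k_lo:k_hi) / sample_rate - seg_start[s]
    values[(k_lo:k_hi) + 1] <- seg_target[s] +
      (v0 - seg_target[s]) * exp(-tt / tau_s)
    # carry the end-of-segment value forward
    v0 <- seg_target[s] +
      (v0 - seg_target[s]) * exp(-seg_dur[s] / tau_s)
  }
  out <- voltage_trace(values, sample_rate)
  attr(out, "step_onsets_s") <- onsets
  attr(out, "steady_dV_mV") <- steady_dV
  out
}

#' Simulate an evoked action-potential train
#'
#' One action-potential template instance is placed at each pulse onset of
#' the protocol; the returned spike train holds the ground-truth peak times.
#'
#' @param protocol A [pulse_train_protocol()].
#' @param cell A [cell_model()].
#' @param sample_rate Sampling rate in Hz (>= 10 kHz so the ~1 ms waveform is
#'   represented).
#' @param tail_s Quiet time appended after the last waveform (s).
#' @return A list with elements `trace` (a [voltage_trace()]) and `spikes`
#'   (a [spike_train()] of ground-truth peak times).
#' @export
simulate_spike_train <- function(protocol, cell, sample_rate = 20000,
                                 tail_s = 0.2) {
  stopifnot(inherits(protocol, "pulse_train_protocol"),
            inherits(cell, "cell_model"))
  check_scalar(sample_rate, "sample_rate")
  if (sample_rate < 10000)
    stop("`sample_rate` must be >= 10 kHz to represent the spike waveform",
         call. = FALSE)
  wf <- spike_waveform(sample_rate, cell$spike_rise_ms, cell$spike_decay_ms,
                       cell$spike_peak_mV)
  wf_dur <- length(wf) / sample_rate
  ipi <- 1 / protocol$frequency_Hz
  if (protocol$n_pulses > 1 && wf_dur > ipi) {
    stop(sprintf(paste0("spike waveform (%.2f ms) outlasts the inter-pulse ",
                        "interval (%.2f ms): pulses 1 and 2 (and all later ",
                        "pairs) overlap"),
                 wf_dur * 1000, ipi * 1000), call. = FALSE)
  }
  onsets <- protocol$onset_s + (seq_len(protocol$n_pulses) - 1) * ipi
  total_s <- protocol$onset_s + (protocol$n_pulses - 1) * ipi + wf_dur + tail_s
  n <- round(total_s * sample_rate)
  values <- rep(cell$resting_mV, n)
  n_rise <- max(1L, round(cell$spike_rise_ms * sample_rate / 1000))
  peak_times <- numeric(length(onsets))
  for (i in seq_along(onsets)) {
    k0 <- round(onsets[i] * sample_rate)  # 0-based start sample
    idx <- k0 + seq_along(wf)             # 1-based indices
    keep <- idx >= 1 & idx <= n
    values[idx[keep]] <- values[idx[keep]] + wf[keep]
    peak_times[i] <- (k0 + n_rise - 1) / sample_rate
  }
  list(trace = voltage_trace(values, sample_rate),
       spikes = spike_train(peak_times, duration_s = total_s,
                            source = "ground-truth"))
}

# Internal: private subthreshold noise, one-pole smoothed (10 ms) white
# noise scaled to the requested SD.
smoothed_noise <- function(n, sd_mV, sample_rate, tau_s = 0.01) {
  if (sd_mV <= 0) return(numeric(n))
  a <- exp(-1 / (sample_rate * tau_s))
  x <- stats::filter(rnorm(n), a, method = "recursive")
  as.numeric(x) * sd_mV * sqrt(1 - a^2)
}

# Internal: double-exponential burst envelope, peak-normalised to 1.
burst_envelope_kernel <- function(sample_rate, rise_s = 0.02, decay_s = 0.2) {
  tt <- seq(0, 5 * decay_s, by = 1 / sample_rate)
  k <- exp(-tt / decay_s) - exp(-tt / rise_s)
  k / max(k)
}

#' Simulate a multi-cell ensemble with common bursts
#'
#' Common burst onsets are drawn as a Poisson process at `burst_rate_Hz`.
#' Within each burst all cells share a spike-time template (a regular train
#' of `spikes_per_burst` spikes, Poisson-distributed with minimum 1, spaced
#' `intra_burst_isi_ms` apart); each cell's copies receive independent
#' Gaussian jitter of SD `sync_jitter_ms`. Independent background spikes are
#' added per cell at `independent_rate_Hz`. The subthreshold voltage is the
#' shared burst envelope (double-exponential, 20 ms rise / 200 ms decay,
#' amplitude `subthreshold_common_amp_mV`) plus private smoothed Gaussian
#' noise; spikes ride on top as waveform instances. Fully reproducible from
#' the model seed: stream 0 drives the shared bursts, stream `i` drives
#' cell `i`.
#'
#' @param model An [ensemble_model()].
#' @param sample_rate Sampling rate in Hz.
#' @param cell A [cell_model()] providing rest and spike template.
#' @return A list of length `n_cells`; each element is a list with `trace`
#'   (a [voltage_trace()]) and `spikes` (a [spike_train()]).
#' @export
simulate_ensemble <- function(model, sample_rate = 10000,
                              cell = cell_model()) {
  stopifnot(inherits(model, "ensemble_model"))
  check_scalar(sample_rate, "sample_rate")
  dur <- model$duration_s
  if (model$burst_rate_Hz > 0 && dur * model$burst_rate_Hz < 1)
    warning("duration is shorter than one expected burst interval",
            call. = FALSE)

  # Shared stream: burst onsets and per-burst spike-time templates.
  set.seed(derive_seed(model$seed, 0))
  n_bursts <- rpois(1, model$burst_rate_Hz * dur)
  burst_onsets <- sort(runif(n_bursts, 0, dur))
  templates <- lapply(seq_len(max(n_bursts, 0)), function(b) {
    k <- max(1, rpois(1, model$spikes_per_burst))
    burst_onsets[b] + (seq_len(k) - 1) * model$intra_burst_isi_ms / 1000
  })

  n <- round(dur * sample_rate)
  env <- numeric(n)
  if (n_bursts > 0) {
    kern <- burst_envelope_kernel(sample_rate)
    for (b in seq_len(n_bursts)) {
      k0 <- round(burst_onsets[b] * sample_rate)
      idx <- k0 + seq_along(kern)
      keep <- idx >= 1 & idx <= n
      env[idx[keep]] <- env[idx[keep]] + kern[keep]
    }
    env <- env * model$subthreshold_common_amp_mV
  }

  wf <- spike_waveform(sample_rate, cell$spike_rise_ms, cell$spike_decay_ms,
                       cell$spike_peak_mV)
  n_rise <- max(1L, round(cell$spike_rise_ms * sample_rate / 1000))

  out <- vector("list", model$n_cells)
  for (i in seq_len(model$n_cells)) {
    set.seed(derive_seed(model$seed, i))
    burst_spikes <- if (n_bursts > 0)
      unlist(lapply(templates, function(tt)
        tt + rnorm(length(tt), 0, model$sync_jitter_ms / 1000)))
    else numeric(0)
    n_bg <- rpois(1, model$independent_rate_Hz * dur)
    bg <- runif(n_bg, 0, dur)
    times <- sort(c(burst_spikes, bg))
    times <- times[times >= 0 & times < dur]
    # enforce a 2 ms refractory gap, keeping the earlier spike
    if (length(times) > 1)
      times <- times[c(TRUE, diff(times) >= 0.002)]
    noise <- smoothed_noise(n, model$subthreshold_noise_mV, sample_rate)
    values <- cell$resting_mV + env + noise
    for (tsp in times) {
      k0 <- round(tsp * sample_rate) - (n_rise - 1)  # peak lands at tsp
      idx <- k0 + seq_along(wf)
      keep <- idx >= 1 & idx <= n
      values[idx[keep]] <- values[idx[keep]] + wf[keep]
    }
    out[[i]] <- list(trace = voltage_trace(values, sample_rate),
                     spikes = spike_train(times, duration_s = dur,
                                          source = sprintf("cell%02d", i)))
  }
  out
}
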