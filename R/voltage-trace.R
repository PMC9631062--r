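#' Membrane-potential trace on a uniform time grid
#'
#' A `voltage_trace` stores membrane potential in mV sampled at a constant
#' rate. Times are implicit: sample `k` (0-based) lies at `k / sample_rate`
#' seconds.
#'
#' @param values Numeric vector of membrane potentials (mV), length >= 2,
#'   all finite.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `voltage_trace` with fields `values`,
#'   `sample_rate` and accessor-computed `times`.
#' @export
voltage_trace <- function(values, sample_rate) {
  check_scalar(sample_rate, "sample_rate")
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a voltage trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("voltage values must all be finite", call. = FALSE)
  structure(list(values = values, sample_rate = sample_rate),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %.4g Hz (%.4g s), range [%.2f, %.2f] mV\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a voltage trace
#'
#' @param v A `voltage_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(v) {
  stopifnot(inherits(v, "voltage_trace"))
  (seq_along(v$values) - 1) / v$sample_rate
}

#' Step-stimulation protocol
#'
#' Describes a family of square stimulus steps delivered after an initial
#' baseline, in current clamp (pA) or voltage clamp (mV). Consecutive steps
#' are separated by `inter_step_s` seconds of return to rest/holding; the
#' default of 0.07 s places the standard measurement windows (which are
#' spaced 170 ms apart) 20--80 ms inside each 100 ms step.
#'
#' @param step_levels Stimulus amplitudes, one per step: pA in current mode,
#'   absolute command potential in mV in voltage mode.
#' @param baseline_s Pre-stimulus baseline duration in seconds.
#' @param step_duration_s Duration of each step in seconds.
#' @param mode `"current"` or `"voltage"`.
#' @param holding_mV Holding potential for voltage mode (mV).
#' @param inter_step_s Recovery interval between consecutive steps (s);
#'   0 gives back-to-back steps.
#' @return A `step_protocol` object.
#' @export
step_protocol <- function(step_levels,
                          baseline_s = 0.1,
                          step_duration_s = 0.1,
                          mode = c("current", "voltage"),
                          holding_mV = -70,
                          inter_step_s = 0.07) {
  mode <- match.arg(mode)
  check_scalar(baseline_s, "baseline_s")
  check_scalar(step_duration_s, "step_duration_s")
  check_scalar(inter_step_s + 1, "inter_step_s + 1") # allow 0
  if (inter_step_s < 0) stop("`inter_step_s` must be >= 0", call. = FALSE)
  if (length(step_levels) < 1L)
    stop("`step_levels` must be non-empty", call. = FALSE)
  structure(list(step_levels = as.numeric(step_levels),
                 baseline_s = baseline_s,
                 step_duration_s = step_duration_s,
                 mode = mode, holding_mV = holding_mV,
                 inter_step_s = inter_step_s),
            class = "step_protocol")
}

#' Default current-clamp step protocol
#'
#' Five current steps from -200 to 200 pA in 100 pA increments, 100 ms each,
#' after a 100 ms baseline.
#' @param ... Overrides passed to [step_protocol()].
#' @return A `step_protocol`.
#' @export
default_current_steps <- function(...) {
  step_protocol(seq(-200, 200, by = 100), mode = "current", ...)
}

#' Default voltage-clamp step protocol
#'
#' Five command steps from -50 to 30 mV in 20 mV increments from a -70 mV
#' holding potential, 100 ms each, after a 100 ms baseline.
#' @param ... Overrides passed to [step_protocol()].
#' @return A `step_protocol`.
#' @export
default_voltage_steps <- function(...) {
  step_protocol(seq(-50, 30, by = 20), mode = "voltage", holding_mV = -70, ...)
}

#' Current pulse-train protocol
#'
#' A train of brief suprathreshold current pulses used to evoke one action
#' potential per pulse.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param amplitude_nA Pulse amplitude in nA.
#' @param pulse_width_ms Pulse width in ms; must be shorter than the
#'   inter-pulse interval.
#' @param frequency_Hz Pulse rate in Hz.
#' @param onset_s Time of the first pulse in seconds.
#' @return A `pulse_train_protocol` object.
#' @export
pulse_train_protocol <- function(n_pulses = 10, amplitude_nA = 2,
                                 pulse_width_ms = 2, frequency_Hz = 25,
                                 onset_s = 0.1) {
  check_scalar(n_pulses, "n_pulses", integer = TRUE)
  check_scalar(frequency_Hz, "frequency_Hz")
  check_scalar(pulse_width_ms, "pulse_width_ms")
  if (pulse_width_ms >= 1000 / frequency_Hz)
    stop("`pulse_width_ms` must be < the inter-pulse interval", call. = FALSE)
  structure(list(n_pulses = as.integer(n_pulses), amplitude_nA = amplitude_nA,
                 pulse_width_ms = pulse_width_ms, frequency_Hz = frequency_Hz,
                 onset_s = onset_s),
            class = "pulse_train_protocol")
}

#' Action-potential waveform template
#'
#' Triangular-exponential template: a linear rise over `rise_ms` followed by
#' an exponential decay with time constant `decay_ms / 2`, truncated after
#' five time constants. With the defaults the full width at half maximum is
#' about 1 ms, matching the millisecond-scale duration of cortical action
#' potentials.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param rise_ms Linear rise time (ms).
#' @param decay_ms Nominal decay duration (ms); the exponential time constant
#'   is half this value.
#' @param peak_mV Peak depolarisation from rest (mV), > 0.
#' @return Numeric vector of mV deflections starting and ending near 0.
#' @export
spike_waveform <- function(sample_rate, rise_ms = 1, decay_ms = 1.5,
                           peak_mV = 80) {
  check_scalar(sample_rate, "sample_rate")
  check_scalar(peak_mV, "peak_mV")
  dt_ms <- 1000 / sample_rate
  n_rise <- max(1L, round(rise_ms / dt_ms))
  tau <- decay_ms / 2
  n_decay <- max(1L, ceiling(5 * tau / dt_ms))
  rise <- seq_len(n_rise) / n_rise * peak_mV
  decay <- peak_mV * exp(-(seq_len(n_decay) * dt_ms) / tau)
  c(rise, decay)
}

#' Passive membrane model of a cell
#'
#' @param resistance_MOhm Input resistance in megaohms.
#' @param tau_membrane_ms Membrane time constant in ms.
#' @param resting_mV Resting potential in mV.
#' @param spike_peak_mV Peak amplitude of the action-potential template (mV
#'   above rest).
#' @param spike_rise_ms,spike_decay_ms Template shape parameters, see
#'   [spike_waveform()].
#' @return A `cell_model` object.
#' @export
cell_model <- function(resistance_MOhm = 100, tau_membrane_ms = 15,
                       resting_mV = -70, spike_peak_mV = 80,
                       spike_rise_ms = 1, spike_decay_ms = 1.5) {
  check_scalar(resistance_MOhm, "resistance_MOhm")
  check_scalar(tau_membrane_ms, "tau_membrane_ms")
  check_scalar(spike_peak_mV, "spike_peak_mV")
  structure(list(resistance_MOhm = resistance_MOhm,
                 tau_membrane_ms = tau_membrane_ms,
                 resting_mV = resting_mV,
                 spike_peak_mV = spike_peak_mV,
                 spike_rise_ms = spike_rise_ms,
                 spike_decay_ms = spike_decay_ms),
            class = "cell_model")
}

#' Multi-cell ensemble model with common bursts
#'
#' Generative description of seizure-like ensemble activity: common burst
#' events shared by all cells (a Poisson process at `burst_rate_Hz`), within
#' which each cell fires jittered copies of a shared spike-time template;
#' independent background spikes; and a subthreshold trace made of a shared
#' burst-locked depolarising envelope plus private noise. Burst statistics
#' are not constrained by any published value and are exposed as
#' configuration.
#'
#' @param n_cells Number of cells (>= 2).
#' @param duration_s Recording duration in seconds.
#' @param burst_rate_Hz Rate of common burst events (Hz).
#' @param spikes_per_burst Mean number of spikes per burst (Poisson, min 1).
#' @param intra_burst_isi_ms Spacing of the shared within-burst spike-time
#'   template (ms).
#' @param sync_jitter_ms SD of per-cell Gaussian jitter applied to shared
#'   burst spike times (ms).
#' @param independent_rate_Hz Per-cell background (non-burst) spike rate (Hz).
#' @param subthreshold_common_amp_mV Peak amplitude of the shared burst
#'   envelope (mV).
#' @param subthreshold_noise_mV SD of per-cell private subthreshold noise
#'   (mV).
#' @param seed Top-level integer seed; all randomness derives from it.
#' @return An `ensemble_model` object.
#' @export
ensemble_model <- function(n_cells = 2, duration_s = 10, burst_rate_Hz = 0.4,
                           spikes_per_burst = 5, intra_burst_isi_ms = 10,
                           sync_jitter_ms = 1, independent_rate_Hz = 1,
                           subthreshold_common_amp_mV = 10,
                           subthreshold_noise_mV = 1, seed = 1L) {
  check_scalar(n_cells, "n_cells", integer = TRUE)
  if (n_cells < 2) stop("`n_cells` must be >= 2", call. = FALSE)
  check_scalar(duration_s, "duration_s")
  for (nm in c("burst_rate_Hz", "sync_jitter_ms", "independent_rate_Hz"))
    if (get(nm) < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), duration_s = duration_s,
                 burst_rate_Hz = burst_rate_Hz,
                 spikes_per_burst = spikes_per_burst,
                 intra_burst_isi_ms = intra_burst_isi_ms,
                 sync_jitter_ms = sync_jitter_ms,
                 independent_rate_Hz = independent_rate_Hz,
                 subthreshold_common_amp_mV = subthreshold_common_amp_mV,
                 subthreshold_noise_mV = subthreshold_noise_mV,
                 seed = as.integer(seed)),
            class = "ensemble_model")
}

#' Write a voltage trace as 2-column CSV
#'
#' Columns `time_s`, `mV`.
#' @param v A `voltage_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_voltage_csv <- function(v, path) {
  stopifnot(inherits(v, "voltage_trace"))
  write.csv(data.frame(time_s = trace_times(v), mV = v$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a voltage trace from 2-column CSV
#'
#' Expects the format written by [write_voltage_csv()]; the sample rate is
#' recovered from the (uniform) time column.
#' @param path CSV file with columns `time_s`, `mV`.
#' @return A `voltage_trace`.
#' @export
read_voltage_csv <- function(path) {
  d <- read.csv(path)
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time column is not a uniform grid", call. = FALSE)
  voltage_trace(d$mV, sample_rate = 1 / dt[1])
}
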