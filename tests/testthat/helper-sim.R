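# Shared fixture builders. Everything is generated in code at test time.

# A stack whose pixels all share one expected photon count per exposure.
constant_stack <- function(lambda, height = 8, width = 8, n_planes = 1000,
                           seed = 1, frame_rate = 9938.4, dark = 0) {
  sensor <- sensor_model(width = width, height = height,
                         frame_rate_Hz = frame_rate,
                         dark_count_rate_cps = dark * frame_rate)
  w <- matrix(as.numeric(lambda > 0), height, width)
  ind <- indicator_model(coupling_per_mV = 0, kinetics_tau_ms = 0,
                         baseline_brightness = max(lambda, 1e-9) * frame_rate)
  rates <- render_photon_rates(rep(1, n_planes), w, ind, sensor)
  sample_bit_planes(rates, seed = seed)
}

# Small random binary stack for serialization tests.
random_stack <- function(height, width, n_planes, seed = 1, p = 0.4) {
  set.seed(seed)
  bit_plane_stack(array(as.integer(runif(height * width * n_planes) < p),
                        dim = c(height, width, n_planes)),
                  frame_rate_Hz = 9938.4,
                  metadata = list(note = "random fixture"))
}

# Forward-model setup used by the spike-fidelity checks: soma-sized sensor
# crop, membrane-annulus footprint, photon budget giving paper-like spike
# SNR (~8) at a 1 kHz effective rate.
spike_budget_setup <- function(target_counts = 4000) {
  sensor <- sensor_model(width = 120, height = 120, dark_count_rate_cps = 0)
  fp <- cell_footprint(sensor, soma_radius_px = 45, annulus_width_px = 12)
  ind <- indicator_model(coupling_per_mV = -0.001, kinetics_tau_ms = 0.5)
  ind$baseline_brightness <- calibrate_brightness(fp, sensor, target_counts)
  list(sensor = sensor, footprint = fp, indicator = ind,
       roi = roi_from_footprint(fp))
}

# Voltage trace -> corrected, 2 kHz low-passed native photon trace.
optical_trace <- function(v, setup, seed, rest = -70) {
  f <- voltage_to_fluorescence(v, setup$indicator, resting_mV = rest)
  rates <- render_photon_rates(hold_to_frames(f, v$sample_rate, setup$sensor),
                               setup$footprint, setup$indicator, setup$sensor)
  stack <- sample_bit_planes(rates, seed = seed)
  lowpass(log_correct_trace(extract_roi_trace(stack, setup$roi)), 2000)
}

# Homogeneous-rate Poisson spike train.
poisson_train <- function(rate_Hz, duration_s, seed, source = "sim") {
  set.seed(seed)
  n <- rpois(1, rate_Hz * duration_s)
  spike_train(sort(runif(n, 0, duration_s)), duration_s, source)
}
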