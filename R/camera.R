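#' Voltage-indicator model
#'
#' Linear coupling between membrane potential and relative fluorescence with
#' optional first-order kinetics. The default coupling is negative
#' (fluorescence dims on depolarisation), matching the polarity of
#' Voltron-family indicators; downstream trace processing can invert
#' polarity so that depolarisation is positive-going.
#'
#' @param coupling_per_mV Fractional fluorescence change per mV (signed).
#' @param kinetics_tau_ms First-order indicator time constant in ms; 0 means
#'   instantaneous.
#' @param baseline_brightness Expected photons per second per unit footprint
#'   weight at resting potential.
#' @return An `indicator_model` object.
#' @export
indicator_model <- function(coupling_per_mV = -0.001, kinetics_tau_ms = 0.5,
                            baseline_brightness = 1e4) {
  if (kinetics_tau_ms < 0)
    stop("`kinetics_tau_ms` must be >= 0", call. = FALSE)
  check_scalar(baseline_brightness, "baseline_brightness")
  structure(list(coupling_per_mV = coupling_per_mV,
                 kinetics_tau_ms = kinetics_tau_ms,
                 baseline_brightness = baseline_brightness),
            class = "indicator_model")
}

#' Binary SPAD sensor model
#'
#' @param width,height Array size in pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param frame_rate_Hz Bit-plane rate in Hz; the exposure time is its
#'   reciprocal.
#' @param dark_count_rate_cps Expected dark events per pixel per second.
#' @param detection_efficiency Dimensionless scale (0, 1] applied to photon
#'   rates.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(width = 320, height = 240, pixel_pitch_um = 8,
                         frame_rate_Hz = 9938.4, dark_count_rate_cps = 100,
                         detection_efficiency = 1) {
  check_scalar(width, "width", integer = TRUE)
  check_scalar(height, "height", integer = TRUE)
  check_scalar(frame_rate_Hz, "frame_rate_Hz")
  if (dark_count_rate_cps < 0)
    stop("`dark_count_rate_cps` must be >= 0", call. = FALSE)
  if (detection_efficiency <= 0 || detection_efficiency > 1)
    stop("`detection_efficiency` must be in (0, 1]", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_pitch_um = pixel_pitch_um,
                 frame_rate_Hz = frame_rate_Hz,
                 exposure_s = 1 / frame_rate_Hz,
                 dark_count_rate_cps = dark_count_rate_cps,
                 detection_efficiency = detection_efficiency),
            class = "sensor_model")
}

#' Membrane-annulus cell footprint
#'
#' Somatic GEVI fluorescence concentrates on the membrane, so the footprint
#' is a bright annulus around a dimmer interior on a zero background.
#'
#' @param sensor A [sensor_model()] giving the frame geometry.
#' @param center_px `(row, col)` of the soma centre (1-based).
#' @param soma_radius_px Radius of the soma in pixels (inner edge of the
#'   annulus).
#' @param annulus_width_px Width of the membrane annulus in pixels.
#' @param interior_weight Relative weight of interior pixels; must be
#'   strictly smaller than the annulus weight of 1.
#' @return A `cell_footprint` with a `height x width` `weight_map`.
#' @export
cell_footprint <- function(sensor, center_px = NULL, soma_radius_px = 14,
                           annulus_width_px = 5, interior_weight = 0.25) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (is.null(center_px))
    center_px <- c((sensor$height + 1) / 2, (sensor$width + 1) / 2)
  if (interior_weight < 0 || interior_weight >= 1)
    stop("`interior_weight` must be in [0, 1) (annulus weight is 1)",
         call. = FALSE)
  r <- sqrt(outer((seq_len(sensor$height) - center_px[1])^2,
                  (seq_len(sensor$width) - center_px[2])^2, "+"))
  w <- matrix(0, sensor$height, sensor$width)
  w[r < soma_radius_px] <- interior_weight
  w[r >= soma_radius_px & r < soma_radius_px + annulus_width_px] <- 1
  structure(list(center_px = center_px, soma_radius_px = soma_radius_px,
                 annulus_width_px = annulus_width_px, weight_map = w),
            class = "cell_footprint")
}

#' Convert membrane potential to relative fluorescence
#'
#' `F_rel(t) = 1 + coupling_per_mV * (V(t) - resting_mV)`, then passed
#' through a first-order low-pass with the indicator time constant (identity
#' when the constant is 0). Output is floored at `epsilon` with a warning if
#' the coupling would drive it non-positive.
#'
#' @param v A [voltage_trace()].
#' @param indicator An [indicator_model()].
#' @param resting_mV Reference potential; defaults to the first sample.
#' @param epsilon Positivity floor.
#' @return Numeric vector of relative fluorescence, same length and rate as
#'   `v`.
#' @export
voltage_to_fluorescence <- function(v, indicator, resting_mV = v$values[1],
                                    epsilon = 1e-6) {
  stopifnot(inherits(v, "voltage_trace"), inherits(indicator, "indicator_model"))
  f <- 1 + indicator$coupling_per_mV * (v$values - resting_mV)
  if (indicator$kinetics_tau_ms > 0) {
    a <- exp(-1000 / (v$sample_rate * indicator$kinetics_tau_ms))
    f <- as.numeric(stats::filter(f * (1 - a), a, method = "recursive",
                                  init = f[1]))
  }
  if (any(f <= 0)) {
    warning("relative fluorescence floored at epsilon (coupling too large)",
            call. = FALSE)
    f[f <= 0] <- epsilon
  }
  f
}

#' Sample-and-hold a trace onto the sensor frame grid
#'
#' Fluorescence is held constant within each exposure, taking the value of
#' the source sample at the exposure start. The source rate must be at least
#' the sensor frame rate.
#'
#' @param values Source samples at `source_rate`.
#' @param source_rate Source sampling rate (Hz).
#' @param sensor A [sensor_model()].
#' @param n_planes Number of exposures; defaults to the number that fit in
#'   the source duration.
#' @return Numeric vector of length `n_planes`.
#' @export
hold_to_frames <- function(values, source_rate, sensor, n_planes = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (source_rate < sensor$frame_rate_Hz)
    stop("source rate must be >= sensor frame rate for sample-and-hold",
         call. = FALSE)
  if (is.null(n_planes))
    n_planes <- floor(length(values) / source_rate * sensor$frame_rate_Hz)
  k <- floor((seq_len(n_planes) - 1) / sensor$frame_rate_Hz * source_rate) + 1
  if (any(k > length(values)))
    stop("requested more planes than the source trace covers", call. = FALSE)
  values[k]
}

#' Per-pixel expected photons per exposure
#'
#' \eqn{\lambda(x,t) = \eta \cdot B \cdot w(x) \cdot F_{rel}(t) \cdot
#' t_{exp} + DCR \cdot t_{exp}} with detection efficiency \eqn{\eta},
#' baseline brightness \eqn{B}, footprint weight \eqn{w}, and dark count
#' rate DCR. The signal term is separable in space and time, so the object
#' stores the two factors; use [rates_matrix()] to materialise.
#'
#' @param f_rel Relative fluorescence per exposure (already on the frame
#'   grid, see [hold_to_frames()]).
#' @param footprint A [cell_footprint()] (or a bare weight matrix).
#' @param indicator An [indicator_model()].
#' @param sensor A [sensor_model()].
#' @return A `photon_rates` object with fields `spatial` (expected signal
#'   photons per exposure per pixel at F_rel = 1, `height x width`),
#'   `temporal` (F_rel per plane), `dark` (dark counts per exposure) and
#'   `sensor`.
#' @export
render_photon_rates <- function(f_rel, footprint, indicator, sensor) {
  stopifnot(inherits(indicator, "indicator_model"),
            inherits(sensor, "sensor_model"))
  w <- if (inherits(footprint, "cell_footprint")) footprint$weight_map
       else footprint
  if (!all(dim(w) == c(sensor$height, sensor$width)))
    stop("footprint weight map does not match sensor dimensions",
         call. = FALSE)
  if (any(w < 0)) stop("footprint weights must be >= 0", call. = FALSE)
  structure(list(
    spatial = sensor$detection_efficiency * indicator$baseline_brightness *
      w * sensor$exposure_s,
    temporal = as.numeric(f_rel),
    dark = sensor$dark_count_rate_cps * sensor$exposure_s,
    sensor = sensor), class = "photon_rates")
}

#' Materialise a photon-rate object as a pixel-by-plane matrix
#'
#' @param rates A `photon_rates` object.
#' @param planes Plane indices to materialise (default all).
#' @return Matrix of \eqn{\lambda} values, `n_pixels x n_planes`, pixels in
#'   column-major (row, col) order.
#' @export
rates_matrix <- function(rates, planes = seq_along(rates$temporal)) {
  stopifnot(inherits(rates, "photon_rates"))
  outer(as.vector(rates$spatial), rates$temporal[planes]) + rates$dark
}

#' Sample binary bit planes from photon rates
#'
#' Each pixel of each plane is an independent Bernoulli draw with
#' \eqn{p = 1 - e^{-\lambda}}: a SPAD pixel reports 1 when at least one
#' Poisson photon (or dark event) arrives during the exposure.
#'
#' @param rates A `photon_rates` object from [render_photon_rates()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @param chunk_planes Number of planes sampled per block (memory control).
#' @return A [bit_plane_stack()].
#' @export
sample_bit_planes <- function(rates, seed, chunk_planes = 1000L) {
  stopifnot(inherits(rates, "photon_rates"))
  check_scalar(seed, "seed", positive = FALSE, integer = TRUE)
  set.seed(as.integer(seed))
  np <- length(rates$temporal)
  h <- rates$sensor$height; w <- rates$sensor$width
  npx <- h * w
  planes <- array(0L, dim = c(h, w, np))
  spatial <- as.vector(rates$spatial)
  for (start in seq(1L, np, by = chunk_planes)) {
    idx <- start:min(np, start + chunk_planes - 1L)
    lam <- outer(spatial, rates$temporal[idx]) + rates$dark
    p <- -expm1(-lam)
    planes[, , idx] <- array(as.integer(runif(npx * length(idx)) < p),
                             dim = c(h, w, length(idx)))
  }
  bit_plane_stack(planes, frame_rate_Hz = rates$sensor$frame_rate_Hz,
                  metadata = list(seed = as.integer(seed),
                                  dark_per_exposure = rates$dark))
}

#' Calibrate baseline brightness for a target ROI count rate
#'
#' Returns the `baseline_brightness` for which the expected number of
#' *detected* counts per bit plane summed over the footprint (at resting
#' fluorescence, including Bernoulli saturation but excluding dark counts)
#' equals `target_counts_per_plane`.
#'
#' @param footprint A [cell_footprint()].
#' @param sensor A [sensor_model()].
#' @param target_counts_per_plane Desired expected ROI counts per plane.
#' @return Brightness in photons per second per unit weight.
#' @export
calibrate_brightness <- function(footprint, sensor, target_counts_per_plane) {
  w <- footprint$weight_map[footprint$weight_map > 0]
  f <- function(b) {
    lam <- sensor$detection_efficiency * b * w * sensor$exposure_s
    sum(-expm1(-lam)) - target_counts_per_plane
  }
  if (target_counts_per_plane >= length(w))
    stop("target exceeds the footprint's pixel count (occupancy saturates)",
         call. = FALSE)
  stats::uniroot(f, lower = 1e-3, upper = 1e12, tol = 1e-8)$root
}
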