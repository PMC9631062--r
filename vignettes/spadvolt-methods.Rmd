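---
title: "Simulating and analysing single-photon voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing single-photon voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadvolt)
```

## The measurement problem

Genetically encoded voltage indicators (GEVIs) report membrane potential as
a small fractional change in fluorescence, with millisecond kinetics and a
tight photon budget. Sampling action potentials above their Nyquist rate
requires kilohertz frame rates, at which conventional cameras are limited
by read noise. A binary SPAD (single-photon avalanche diode) array sidesteps
read noise entirely: each pixel reports, per ~100 µs exposure, whether at
least one photon (or dark event) arrived. The raw data are *bit planes* —
binary frames at ~10 kHz — and every downstream quantity is built by
counting 1s in space (ROI sums, composed images) and time (temporal
binning). Because the noise is purely photon shot noise, frames can be
binned after acquisition to any effective rate without a noise penalty
beyond the unavoidable \(\sqrt{N}\).

`spadvolt` implements both directions of this measurement:

* a **forward simulator** — membrane-potential dynamics → GEVI fluorescence
  → per-pixel Poisson photon rates → Bernoulli bit planes — with exactly
  the photon statistics the analysis assumes, and
* the **inverse pipeline** — bit planes → ROI traces → pixel-response
  correction → filtering/binning → subthreshold and spiking metrics →
  ensemble synchrony statistics with shuffle-derived null bands.

Having both in one package means every analysis stage can be validated
against ground truth without any real recording.

## The photon model

A pixel with footprint weight \(w(x)\) viewing relative fluorescence
\(F_{rel}(t)\) has expected photons per exposure

\[\lambda(x,t) = \eta\, B\, w(x)\, F_{rel}(t)\, t_{exp}
  + \mathrm{DCR}\, t_{exp},\]

with detection efficiency \(\eta\), baseline brightness \(B\), exposure
\(t_{exp} = 1/f_{frame}\) and dark count rate DCR. The binary pixel fires
with probability \(p = 1 - e^{-\lambda}\). This saturating ("logarithmic")
response is inverted exactly by \(\hat\lambda = -\ln(1-\hat p)\), which is
what `correct_image()` applies per pixel (after which the expected dark
contribution is subtracted and the result clipped at zero) and what
`log_correct_trace()` applies to ROI sums, treating the ROI as \(M\)
identical pixels. Saturated occupancies are capped at
\(-\ln\!\big(1/(2n)\big)\) so downstream statistics stay finite.

Fluorescence couples linearly to voltage,
\(F_{rel} = 1 + c\,(V - V_{rest})\), optionally passed through a
first-order lag with the indicator time constant. The default coupling is
negative (−0.001 per mV), matching Voltron-family indicators; the pipeline
can mirror traces about their baseline so depolarisation is positive-going
before metrics and detection.

Simplifications relative to real sensors, all deliberate: a global (not
rolling) shutter, since the ≤100 µs row skew is far below analysis
timescales; fluorescence held constant within one exposure; no afterpulsing,
crosstalk or optical point-spread function. Passing tests therefore
demonstrates correctness of the *statistical* chain, not of optics.

## Cell and protocol models

`cell_model()` is a passive membrane: input resistance \(R\) (default
100 MΩ), time constant \(\tau_m\) (default 15 ms), rest −70 mV, plus a
stereotyped action-potential template (1 ms linear rise to +80 mV,
exponential decay with 0.75 ms constant; ~1 ms FWHM). Current steps relax
exponentially toward \(V_{rest} + IR\); voltage-clamp commands are followed
with a fixed 1 ms settling constant.

The standard step protocols place 100 ms steps after a 100 ms baseline.
The canonical measurement windows (120–180, 290–350, 460–520, 630–690,
800–860 ms) are spaced 170 ms apart, so consecutive steps are separated by
a 70 ms return to rest (`inter_step_s`, configurable; 0 gives back-to-back
steps). Each window then sits 20–80 ms inside its step. In current clamp
the 0 pA level produces no deflection and has no window. A `tail_s` of
quiet recording is appended after step and pulse protocols so that
post-onset analysis segments and rolling detector windows fit inside the
trace — as they would in a real recording that simply keeps running.

The ensemble generator emulates seizure-like coordination: common burst
onsets (Poisson, default 0.4 Hz), a shared within-burst spike-time template
jittered per cell (Gaussian SD `sync_jitter_ms`), independent background
spikes, and a subthreshold trace made of a shared burst envelope
(double-exponential, 20 ms rise / 200 ms decay) plus private smoothed
noise. No published value constrains the burst statistics, so they are
plain configuration with defaults chosen to look like sparse interneuron
bursting; the generator's purpose is controlled ground truth for the
synchrony statistics, not biophysical realism. All randomness derives from
one seed (stream 0: shared bursts; stream *i*: cell *i*), so replay is
bit-identical.

## The trace pipeline

For each bit plane, counts are summed within a binary ROI mask and the
per-plane sums concatenated into an optical trace at the native rate
(9938.4 Hz by default). The processing chain is then:

1. logarithmic-response correction of the ROI sums (traces receive no dark
   subtraction — a constant dark offset cancels in ΔF and is absorbed by
   baseline normalisation);
2. zero-phase 4th-order Butterworth low-pass at 2 kHz (forward–backward,
   so spike timing is not skewed; DC gain exactly 1);
3. temporal binning: non-overlapping means of \(N\) consecutive samples,
   effective rate = native/\(N\) (100 Hz for subthreshold analysis, 1 kHz
   for spikes), trailing remainder dropped;
4. for subthreshold work, linear detrending (OLS line subtraction);
5. for spiking work, *spike-band isolation*: the trace minus its 10 Hz
   zero-phase low-pass copy, then binned to 1 kHz. The subtraction reading
   (high-pass by subtraction) is the default because a literal second
   low-pass at 10 Hz would retain the subthreshold events rather than
   remove them; the literal mode is available as `mode = "direct"`.

The filter family and order are package choices (nothing in the definition
of the chain forces Butterworth); zero phase is the binding requirement.
Forward–backward filtering uses steady-state initial conditions and odd
reflection padding sized by the slowest pole, so constants and ramps pass
exactly — important because the 10 Hz stage operates 3 decades below the
sampling rate.

Shot-noise bookkeeping: for a constant source, the SD of the binned ROI
trace scales as \(N^{-1/2}\), so dF/F is invariant under binning while SNR
grows — the property that lets the effective frame rate be chosen per
biological question after acquisition.

## Metrics

* **Step dF/F and SNR** (100 Hz trace): baseline fluorescence \(F\) is the
  mean over the first 100 ms; per response window
  \(\Delta F = \text{mean(window)} - F\), \(\Delta F/F = \Delta F / F\),
  \(\mathrm{SNR} = \Delta F / \mathrm{SD(baseline)}\). Windows map to
  samples half-open \([start, end)\) at the effective rate, 0-based. The
  baseline SD is computed *after* binning, at the analysis rate — the SD
  depends on rate, so this convention is fixed and documented.
* **F–V linearity**: regression through the origin,
  slope \(=\sum xy / \sum x^2\), with the uncentred
  \(R^2 = 1 - \sum(y-\hat y)^2 / \sum y^2\) (the standard convention when
  the intercept is forced). ΔV is measured from the electrical trace over
  the same windows, pairing the two readouts identically.
* **Time constants**: least-squares fit of \(y = A + B e^{-t/\tau}\) over
  the 100 ms after step onset, initialised from the segment endpoints and
  solved by Levenberg–Marquardt (relative tolerance 1e-8, ≤200
  iterations). Degenerate segments and \(\tau \notin (0.1\,\mathrm{ms},
  1\,\mathrm{s})\) return a failure record rather than an error. Optical
  fits use the 1 kHz binned trace; 100 Hz leaves too few samples per
  segment.
* **Spike dF/F and SNR**: per spike, peak intensity minus baseline
  fluorescence of the same trace, divided by \(F\) (dF/F) or by the
  baseline SD (SNR); trace-level values are means over spikes.

## Spike detection and synchrony statistics

The detector has three free parameters plus a refractory gap. The local
baseline is a rolling median over `window_samples`; local noise is
1.4826 × rolling median of absolute deviations (a rolling MAD, robust to
the spikes themselves). Candidates are local maxima exceeding both
`sd_threshold` × noise and an absolute floor; of peaks closer than
`refractory_ms`, the larger wins. Defaults: window 301 samples (0.3 s at
1 kHz), threshold 4 SD, refractory 4 ms. The window is deliberately long
relative to a 100 ms pulse train: with a window comparable to the burst,
spike samples contaminate the rolling MAD (up to ~40% duty at 100 Hz) and
inflate the threshold. These are operating-point defaults, not fitted
constants; in practice they are tuned per preparation against
simultaneous electrophysiology.

Scoring against ground truth uses greedy nearest-first one-to-one matching
within ±2 ms (one millisecond-scale bin); unmatched detections are false
positives, unmatched truth spikes false negatives. The matching is
symmetric: swapping the roles swaps FP and FN.

The PSTH counts target-cell spikes in half-open lag bins around each
reference spike, summed over reference spikes (the sum, not a per-event
average), with an odd number of bins so one bin is exactly centred on zero
lag — 50 ms window / 2 ms bins for millisecond-level structure, 1 s /
100 ms for slower coordination. Its null band comes from 100 shuffles that
redraw both trains' spike times uniformly (counts preserved; ISI shuffling
is available), recording the per-bin mean and 5–95% envelope.

Subthreshold correlation z-scores both 100 Hz detrended traces and
computes the biased (divisor \(n\)) cross-correlation over all lags, so a
trace against itself gives exactly 1 at zero lag; epoch curves are
averaged when ten 10 s epochs are supplied. Its null band pairs traces
from *different* sources — independent simulations standing in for cells
from different slices — since shuffling cannot destroy slow
autocorrelation within a trace.

## Photon budgets and problem sizes

The real recordings' absolute photon flux is not constrained by any
published number, so budgets are configuration with calibrated defaults
(`calibrate_brightness()` solves for the brightness that yields a target
expected ROI count per plane):

* subthreshold/linearity work: a soma-sized 48×48 px crop, annulus
  footprint (r = 14 px, width 5), 300 expected ROI counts per plane —
  at 100 Hz this leaves ~0.6% relative noise per sample and reproduces
  forced-origin \(R^2 \approx 0.99\) over 9 cells;
* spike work: a 120×120 px crop, annulus r = 45 px, width 12 (~10⁴
  member pixels), 4000 expected ROI counts per plane — at 1 kHz this
  yields single-spike SNR ≈ 8–11 and dF/F ≈ 4%, the published
  single-spike operating range for this indicator class.

Simulating a crop rather than the full 320×240 array changes nothing
statistically (pixels are independent) and keeps the test suite inside a
minute; the container, file format and pipeline accept full-frame stacks
unchanged. The test suite's stochastic checks run at sizes (10⁴–10⁵
planes, ≤50 calibration seeds) where binomial/Poisson oracle tolerances
are meaningful at 3σ.

## Numerical and degenerate-input choices

* Saturated occupancy caps: image \(-\ln(1/(2n))\), trace
  \(-M\ln(1/(2M))\).
* Relative fluorescence is floored at a configurable ε (warning) if the
  coupling would drive it non-positive.
* Binning drops trailing remainders rather than averaging partial bins.
* `fit_tau` failures are values, not exceptions, so batch fits can be
  filtered.
* Window-to-sample maps use half-open intervals with a 1e-9 guard against
  floating-point edge ties.
* Empty spike sets: metrics return empty results; an empty *reference*
  train makes a PSTH meaningless and errors.

## The `.spb` container

The paper-of-record data format for bit planes here is a packed-bit file:
a 32-byte little-endian header (magic `SPB1`, version, width, height,
plane count, frame rate as float64, flags, metadata length), optional
UTF-8 JSON metadata, then planes in time order, row-major, bits MSB-first,
each plane padded to a byte boundary — 320×240×10⁴ planes = 96 MB of
payload. Round-trips are bit-exact, including odd widths; multipage 8-bit
TIFF import/export is provided for interchange.

## Known limitations

* The membrane model is passive; spikes are pasted templates, not
  conductance dynamics, so spike-shape-dependent effects (e.g. amplitude
  accommodation) are out of reach.
* The ensemble generator's burst statistics are invented configuration;
  synchrony results validate the *statistics*, not any biological claim.
* Dark-count correction assumes a known scalar rate; per-pixel DCR maps
  are accepted but estimating them from dark frames is left to the user.
* The rolling-MAD noise estimate degrades when spikes occupy a large
  fraction of the detector window; long windows (or sparser activity) are
  assumed.

## A worked end-to-end run

```{r, eval = FALSE}
library(spadvolt)

# 9-cell current-clamp linearity benchmark (the package's headline check)
res <- simulate_fv_linearity(n_cells = 9, seed = 1)
mean(res$r_squared)    # ~0.992 with the default budget

# one configured experiment, from config to manifest
cfg <- list(kind = "pulse", seed = 1, out_dir = "pulse_run",
            sensor = list(width = 120, height = 120,
                          dark_count_rate_cps = 0),
            footprint = list(soma_radius_px = 45, annulus_width_px = 12),
            target_counts_per_plane = 4000)
summary <- run_experiment(cfg)
summary$detection      # tp = 10, fp = 0, fn = 0
```
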