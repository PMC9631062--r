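Package: spadvolt
Title: Simulation and Analysis of Single-Photon (SPAD) Voltage Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorescence voltage imaging with binary single-photon
    avalanche diode (SPAD) array sensors. Provides a forward simulator that
    turns membrane-potential dynamics into genetically encoded voltage
    indicator (GEVI) fluorescence, per-pixel Poisson photon rates, and
    Bernoulli-sampled binary bit planes; a lossless packed-bit container for
    bit-plane stacks with TIFF interchange; image composition with dark-count
    and logarithmic pixel-response correction; ROI trace extraction with
    shot-noise-aware temporal binning, zero-phase filtering and detrending;
    step-response metrics (dF/F, SNR, through-origin F-V regression,
    exponential time-constant fits); and spike detection with ground-truth
    scoring, shuffle-null peristimulus time histograms and normalized
    cross-correlograms for ensemble synchrony analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
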