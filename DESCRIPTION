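Package: axospindle
Title: Spindle Oscillation and Conduction-Delay Analysis for Axonal
    Microelectrode-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 10-16 Hz spindle oscillations recorded from
    single axons in microfluidic tunnels of a reconstituted four-subregion
    hippocampal network (EC, DG, CA3, CA1) on a microelectrode array. Provides
    signal conditioning (Kaiser FIR decimation, Butterworth and elliptic
    band-pass filters, Hilbert envelope and phase, Morse-wavelet scalograms),
    envelope-threshold spindle detection, slow-wave trough and slow-oscillation
    epoch detection, spike detection with cross-electrode matching to estimate
    axonal conduction delays and velocities, spindle-within-slow-wave nesting
    with log-log lag fitting, spike-phase coupling with the Hodges-Ajne omnibus
    test, inter-channel spindle-envelope correlations, log-binned Gaussian
    fitting of event-metric distributions, and a synthetic tunnel-recording
    generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
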