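Package: spikebench
Title: Bio-Inspired Ground-Truth Benchmark Generator for Extracellular
    Multi-Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates fully annotated, parameterisable benchmark datasets of
    extracellular multi-unit recordings for evaluating spike sorting, event
    detection and denoising tools. Composite signals are built per electrode
    as the sum of three components: spike activity rendered from a virtual
    tissue volume of randomly placed pyramidal cells and interneurons through
    a distance-attenuation law, non-stationary slow oscillations (< 300 Hz,
    zero-phase 10th-order Butterworth), and injected artefacts of three
    documented classes (mechanical shocks, mastication, grooming) with
    boundary-smoothed insertion and cross-channel coincidence detection.
    Includes a Bartlett averaged-periodogram validation stack with
    per-frequency standard errors and local polynomial smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
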