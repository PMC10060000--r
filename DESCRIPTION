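Package: desimrm
Title: Targeted DESI-MRM Mass Spectrometry Imaging: Simulation, Reconstruction and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted desorption electrospray ionization (DESI)
    mass spectrometry imaging acquired in multiple reaction monitoring (MRM)
    mode on a triple quadrupole. Models acquisition timing and line-scan
    geometry, reads and writes per-transition chronograms, reconstructs ion
    images with line-to-line jitter re-alignment, normalizes intensities to
    dwell time, computes region-of-interest statistics with exact Mann-Whitney
    testing, and classifies pixels into tissue types by maximum margin
    criterion projection and PLS-DA with cross-validation. A mechanistic
    desorption/ionization kinetics simulator generates synthetic chronograms
    with ground truth so the full chain runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    tools,
    yaml,
    png,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mixOmics,
    withr
Config/testthat/edition: 3
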