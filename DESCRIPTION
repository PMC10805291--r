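Package: quantacam
Title: Animal-View Multispectral Imaging from Dual-Camera Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts paired ultraviolet and visible camera recordings into
    animal photoreceptor quantum-catch imagery. Provides wavelength-gridded
    spectra and catch integrals, camera sensor-sensitivity estimation from
    monochromator sweeps, fiducial-marker colour-card detection, S-Log3
    linearization and grayscale normalization, two-stage spatial and temporal
    image alignment by enhanced-correlation-coefficient maximization, an
    empirically fitted camera-to-receptor transformation matrix with accuracy
    diagnostics, receptor-noise-limited colour distances, false-colour
    rendering, a synthetic optical simulator with known ground truth, and a
    JSON-serializable directed-acyclic-graph pipeline engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    EBImage,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
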