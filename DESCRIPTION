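Package: ssaxs
Title: Scanning Small-Angle X-Ray Scattering Analysis of Soft Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for scanning small-angle X-ray scattering
    (sSAXS) raster maps of soft tissue. Segments collagenous, muscular and
    other connective-tissue regions from the low-q intensity exponent, fits
    the pi-periodic cosine model of azimuthal intensity to map fibre
    orientation, extracts the collagen meridional D-period, peak widths,
    I6/I5 and overlap/D-period ratios from Gaussian fits of the Bragg
    orders, fits the myofilament hexagonal-lattice equatorial doublet (d10,
    d11, I11/I10), and compares per-region parameter distributions across
    samples with rank-based tests. Includes a forward simulator of reduced
    scans (and raw detector frames) with preservation-method presets that
    provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    minpack.lm,
    png,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
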