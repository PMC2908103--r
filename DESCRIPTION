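Package: scancal
Title: Microarray Scanner Response Calibration with an
    Autofluorescence-Aware Power Law
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models microarray scanner (photomultiplier) response to
    fluorophore surface density as a power law plus an autofluorescence
    offset, SI = B*x^a + g, and fits the three parameters to
    calibration-slide scans by relative (weighted) least squares suited
    to data spanning many orders of magnitude. Includes a simulator for
    Full Moon BioSystems-style calibration slides (two-fold dilution
    series, buffer and blank columns, multiplicative noise, 16-bit
    detector saturation), readers and writers for GAL (GenePix Array
    List) layouts and spot-intensity tables, a manual-versus-layout
    consistency audit, bootstrap uncertainty intervals, and diagnostics
    for gain invariance of the autofluorescence offset, channel
    invariance of the response curvature, usable density ranges, and
    two-channel ratio constancy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
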