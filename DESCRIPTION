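Package: petprecision
Title: Precision of Quantitative PET Metrics via Digital Phantom Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates repeated PET acquisitions of digital analogs of the
    NEMA NU-2 image-quality phantom and a gray/white-matter brain phantom,
    with and without random rigid repositioning, at matched count statistics
    under decay-compensated frame schedules. Quantifies each replicate with
    SUVmax, SUVpeak (1 mL fractional-coverage spherical VOI search) and
    SUVmean over background-corrected 50% isocontours, converts to recovery
    coefficients, and compares the precision of repositioned versus
    stationary series with two-sample variance F-tests. Also measures real
    PET volumes supplied as NIfTI-1 files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
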