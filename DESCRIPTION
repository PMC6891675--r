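Package: RamanHoney
Title: Chemometric Calibration of Honey Physicochemical Properties from
    Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A complete chemometric workflow for predicting ten
    physicochemical honey properties (pH, moisture, total soluble solids,
    free/lactonic/total acidity, electrical conductivity, Redox potential,
    hydroxymethylfurfural and ash) from dispersive Raman spectra. Provides
    S4 containers for spectral matrices and property tables, spectral
    preprocessing operators (alignment, asymmetric-least-squares baseline
    correction, Savitzky-Golay smoothing and derivatives, normalization,
    log10, standard normal variate, centering and autoscaling) composable
    into fit/apply recipes, a from-scratch NIPALS PLS1 implementation with
    loading-region interpretation, Kennard-Stone calibration/validation
    splitting, leave-five-out cross-validation for latent-variable
    selection, the SEC/SEP/R-squared/paired-t validation statistics, and a
    seeded synthetic Raman spectrum generator that emulates the band
    structure and property distributions of multifloral honey so the whole
    pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
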