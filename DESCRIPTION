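Package: irtissue
Title: Infrared Spectral Classification of Liver Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for attenuated-total-reflection (ATR)
    FT-IR tissue diagnostics: preprocessing of fiber-probe absorbance
    spectra and focal-plane-array spectroscopic images (range restriction,
    two-point baseline, area and min-max normalization, atmospheric
    compensation, outlier filtering), genetic-algorithm selection of
    discriminative wavenumber windows, quadratic discriminant
    classification with per-sample posterior aggregation, k-fold
    cross-validation, confusion-matrix metrics, and per-wavenumber
    two-sample t-tests. Includes a synthetic spectrum generator that
    emulates the biochemical contrasts between normal liver, hepatocellular
    and cholangiocellular carcinoma, and metastases (glycogen, amide-III /
    collagen, and CH deformation bands), so the full pipeline is testable
    end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
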