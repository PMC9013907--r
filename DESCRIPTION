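Package: hairEtG
Title: Quantification, Validation and Interpretation of Hair Ethyl
    Glucuronide GC-MS/MS Assays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted GC-EI-MS/MS quantification of ethyl
    glucuronide (EtG) in hair: selected-reaction-monitoring (SRM)
    chromatogram simulation and peak integration, RMS baseline-noise
    estimation and ion-ratio identification checks, unweighted calibration
    with homoscedasticity (Fisher), lack-of-fit and Mandel linearity
    diagnostics, detection limits by signal-to-noise and by the Hubaux-Vos
    calibration prediction-band algorithm, 2^k full-factorial
    design-of-experiments effect estimation for sample-pretreatment
    optimization, intra-/inter-day precision and trueness reporting, and
    censoring-aware interpretation of cohort results against the Society
    of Hair Testing 30 pg/mg cut-off.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
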