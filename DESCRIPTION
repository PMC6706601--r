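Package: nitroquant
Title: Internal-Standard Quantification of Nitroaromatic Explosives from
    MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Targeted quantification of nitroaromatic explosives (TNT,
    aminodinitrotoluenes, dinitrotoluenes, trinitrobenzene, dinitrobenzene,
    nitrotoluene) in soil extracts from negative-mode MALDI-TOF mass
    spectra, using 5-chloro-2,4-dinitrotoluene as internal standard.
    Provides a seeded synthetic-spectrum generator with known ground truth,
    spectrum preprocessing (mass recalibration, total-ion-current
    normalization, peak detection, targeted ion extraction),
    internal-standard calibration by classical least squares with an
    optional TNT-interference bivariate model, sequential inversion for
    interference-corrected quantification, extract-to-soil concentration
    conversion, and specificity validation by principal component analysis
    and two-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
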