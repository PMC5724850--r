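Package: normES
Title: Reconstruction-Robust CT Emphysema Scoring and Mortality Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies pulmonary emphysema on chest CT with the -950 HU
    density mask and harmonizes the score across reconstruction settings:
    slice resampling to a common thickness, frequency-band energy
    normalization toward a reference kernel, and per-slice filtering of
    sub-5 mm2 low-attenuation clusters (normES versus the conventional
    origES). Includes threshold-based lung segmentation, digital chest
    phantoms rendered under simulated reconstruction kernels, simulated
    case-control survival cohorts, and the censored-data evaluation
    statistics used to compare markers against mortality: weighted
    Kaplan-Meier curves, pairwise log-rank tests, time-dependent ROC AUC
    with inverse-probability-of-censoring weights, bootstrap AUC
    differences, and the continuous net reclassification improvement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
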