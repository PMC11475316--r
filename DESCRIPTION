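Package: mmoct
Title: Quantitative Multimodal OCT Analysis: Attenuation Mapping,
    Compression Elastography and Diagnostic Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multimodal optical coherence
    tomography (OCT) data of soft tissue. Implements depth-resolved
    attenuation-coefficient mapping for co- and cross-polarization channels
    with additive-noise and sensitivity compensation, phase-sensitive
    compression optical-coherence-elastography (vector-method interframe
    strain, stress calibration via a linear reference silicone layer, tangent
    Young's modulus at a prescribed stress), region-of-interest group
    statistics (median [Q1; Q3] descriptives, exact and approximate
    Mann-Whitney tests with Bonferroni correction) and ROC-based diagnostic
    threshold selection. Ships a speckle phantom generator with known
    per-layer ground truth (attenuation per channel, linear or exponential
    stress-strain laws) so every estimator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
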