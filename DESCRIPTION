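Package: octadme
Title: OCTA Macular Biomarkers and Treatment-Response Analysis for Diabetic Macular Edema
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies en-face optical coherence tomography angiography (OCTA)
    biomarkers of the macula -- skeleton-based vessel density, perfusion density
    and foveal avascular zone (FAZ) morphometrics with axial-length magnification
    correction -- and models longitudinal treatment response of diabetic macular
    edema to intravitreal anti-VEGF therapy (delta-from-baseline outcomes,
    threshold dichotomization, univariate tests and mixed-effects backward
    elimination). A synthetic-data module generates capillary-network angiograms
    with known ground truth and longitudinal eye-within-patient cohorts so the
    entire pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
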