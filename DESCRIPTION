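Package: cochleaST
Title: Scala Tympani Geometry and Cochlear-Implant Insertion-Force Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for parametrising scala tympani (ST) lumen geometry from a
    triangulated surface mesh and basilar-membrane landmarks: best-fit basal
    plane, perpendicular cross-section extraction, centreline construction,
    double-exponential spiral fitting, and conversion between electrode
    insertion distance and angular insertion depth. Supports procedural shape
    manipulation (volumetric scaling, centreline flattening, artificial
    non-planarity, spiral-curvature reshaping, cross-section uniformisation),
    watertight mesh reconstruction by lofting ordered cross-sections,
    print-model preparation, and nominal-actual surface-deviation analysis.
    Includes a Capstan friction model of cochlear-implant insertion forces
    with trace simulation, fixed-tip-force exponential fitting, relaxation
    metrics, and group comparison of exponential coefficients, plus a
    parametric synthetic scala tympani generator so the full in-silico
    experiment pipeline runs without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
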