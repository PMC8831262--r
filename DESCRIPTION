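Package: shearplaque
Title: Wall Shear Stress and Histological Plaque Composition Co-Localization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to relate pulsatile wall shear stress (WSS) metrics on
    carotid lumen surfaces to histologically determined plaque composition.
    Implements the Womersley pulsatile-flow solution with waveform scaling to
    a target time-averaged WSS, Carreau-Yasuda blood rheology, per-vertex
    TAWSS and OSI computation, axial-window and 45-degree radial-sector
    binning around a vessel centerline, per-sector quantification of necrotic
    core, fibrin, macrophage area and fibrous-cap thickness from class-coded
    histology masks, registration quality control (Dice coefficient, average
    Hausdorff distance, rigid 2D contour alignment), and patient-specific
    tertile linear mixed-effects statistics with Bonferroni-adjusted pairwise
    comparisons. A synthetic-study generator with analytic ground truth makes
    the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
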