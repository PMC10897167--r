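Package: matstrain
Title: Nanoscale Material Strain Analysis for In Situ X-Ray Scattering of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting collagen and mineral material strains from
    synchrotron small- and wide-angle X-ray scattering (SAXS/WAXD) frames
    recorded during in situ tensile testing of bone.  Includes a synthetic
    detector-frame generator with known ground truth, azimuthal/radial
    reduction with silver-behenate geometry calibration, Bragg peak fitting
    and d-spacing strain series, the second Legendre (P2) orientation
    parameter, CCD-marker tissue strain with time matching, dose-cap and
    sample-exclusion bookkeeping, pooled material-vs-tissue strain slope
    regression with extra sum-of-squares F tests and the slope-sum composite
    diagnostic, three-point-bend whole-bone metrics with elliptical
    moment-of-inertia material properties, and the factorial ANOVA with
    Fisher's LSD and Bonferroni-corrected alpha statistical framework used
    alongside them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
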