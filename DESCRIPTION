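Package: heatstrain
Title: Occupational Heat Stress, Maternal Heat Strain and Fetal Strain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the pathway from environmental heat stress to
    maternal heat strain and acute fetal strain in pregnant outdoor workers.
    Computes the wet bulb globe temperature (WBGT), the universal thermal
    climate index (UTCI) via the operational sixth-order polynomial, and
    occupational exposure categories; scores maternal heat strain with a
    modified physiological strain index built on chest skin temperature and
    heart rate; estimates physical activity energy expenditure from heart-rate
    features with an observational METs fallback; derives the umbilical artery
    resistance index and a composite binary fetal-strain outcome from fetal
    heart rate series and Doppler velocities; and fits repeated-measures
    total-effect and direct-effect models (linear for fetal heart rate,
    logistic for fetal strain) with cluster estimating equations, spline
    versus linear exposure comparison, and supporting descriptive statistics.
    A seeded synthetic cohort generator with a mediated
    stress-strain-fetal structure makes the full pipeline testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    splines,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
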