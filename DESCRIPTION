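Package: pbbm
Title: Physiologically Based Biopharmaceutics Modeling for Fixed-Dose
    Combination Bioequivalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic oral-absorption modeling linking in vitro
    dissolution to in vivo exposure for immediate-release fixed-dose
    combination products. Implements Weibull dissolution kinetics (with a
    hazard form suitable for ODE coupling), a six-segment gastrointestinal
    transit and absorption model with pH-dependent solubility, saturable
    carrier-mediated uptake and Michaelis-Menten renal tubular secretion,
    a reduced two-compartment systemic disposition, virtual-population
    2x2 crossover bioequivalence simulation with two within-subject
    gastrointestinal states, local relative sensitivity analysis, and
    dissolution safe-space exploration over the 50 percent-dissolution
    time. Includes synthetic-data generators for dissolution profiles and
    clinical concentration-time datasets so the full workflow runs
    self-contained. The bundled drug presets parameterize a metformin +
    glyburide combination tablet.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
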