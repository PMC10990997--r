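Package: iapflow
Title: Quantitative Iodoantipyrine Autoradiographic Cerebral Blood Flow Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative regional cerebral blood flow (rCBF)
    measurement by carbon-14 iodoantipyrine autoradiography using the
    indicator-fractionation (tissue-equilibration) tracer-kinetic model.
    Implements the forward tissue-uptake model Ci(T) = lambda K int C_A(t)
    exp(-K(T-t)) dt and its numerical inversion to flow per unit tissue
    mass, densitometric calibration of autoradiograms against precalibrated
    isotope standards, quench correction of arterial blood counts, group
    statistics (mean +/- SEM, one-way and two-way ANOVA with Tukey HSD post
    hoc, Western-blot phospho/total normalization), and a seeded synthetic
    study generator for end-to-end parameter-recovery validation of a
    strain-by-treatment experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
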