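Package: uptick
Title: Stochastic Simulation of Basal comK Promoter Dynamics in Bacillus subtilis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transient rise and fall ("uptick") in basal comK promoter
    activity during entry of Bacillus subtilis into stationary phase. Builds a
    promoter-occupancy reaction network in which phosphorylated Spo0A first
    anti-represses the constitutive repressor Rok at activation sites A1-A3 and
    then represses directly at operator sites R1-R2, superimposed on a global
    core-promoter activity profile. Networks are simulated exactly with
    Gillespie's stochastic simulation algorithm (compiled core), ensembles are
    reduced to mean transcription-rate curves and mutant amplitude ratios, and
    intrinsic versus extrinsic expression noise is quantified by the correlation
    between two identical promoters sharing one cell's regulator pools. Also
    includes a single-cell two-reporter cytometry pipeline (threshold
    calibration, competence classification, binned competent-fraction profiles,
    boundary proportion tests) together with a synthetic per-cell intensity
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
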