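Package: peepflow
Title: Regional Ventilation Distribution and Respiratory Mechanics During
    Assisted Spontaneous Breathing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for PEEP titration experiments during
    neurally adjusted ventilatory assist (NAVA). Reads synchronized
    airway/esophageal/gastric pressure and flow waveforms together with
    electrical impedance tomography (EIT) sequences, segments spontaneous
    breathing into breaths from the flow signal, computes tidal volumes by
    flow integration, fits per-breath compliance and resistance by
    multilinear regression of transpulmonary pressure on volume and flow,
    reduces EIT frames to four anterior-to-posterior regions of interest,
    derives tidal impedance changes, proportional tidal volume
    distribution and the dependent fraction of ventilation (DFV), and
    selects the PEEP level whose DFV is nearest 50%. Includes the paired
    nonparametric statistical battery (exact Wilcoxon signed-rank,
    Mann-Whitney, normality routing, Bonferroni thresholds, linear
    regression on PEEP) and a calibrated generator of NAVA breathing and
    EIT data for a full incremental/decremental PEEP ladder protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
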