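Package: lungquant
Title: Quantification Stack for Murine Emphysema Studies: Morphometry,
    Respiratory Mechanics and qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative pipeline of mouse emphysema and
    lung-senescence studies: grid-intercept mean linear intercept (MLI)
    morphometry of alveolar histology with field selection, quality control
    and background correction; estimation of respiratory-mechanics
    parameters from snapshot perturbations (single-compartment R, C, E),
    forced-oscillation impedance spectra (constant-phase Rn, I, G, H,
    hysteresivity) and quasi-static pressure-volume loops (Salazar-Knowles
    A, B, K with static compliance, elastance and hysteresis), including
    the r-squared acceptance rule and average-of-three aggregation; qPCR
    standard-curve quantification with the average telomere length ratio
    (T/S) and reference-normalized relative expression; and the group
    statistics layer (mean +/- SD summaries, pooled two-tailed t tests).
    A synthetic-data module generates alveolar tissue masks with known
    chord-length ground truth, mechanics records from known parameters,
    and qPCR plates from a log-linear amplification model, so the whole
    stack is testable end to end against built-in oracles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
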