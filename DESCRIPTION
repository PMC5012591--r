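Package: motilitymap
Title: Mapping Escherichia coli Swimming Phenotype to Chemotaxis Protein Numbers
Version: 0.1.0
Authors@R:
    person("Motility Map", "Developers", email = "motilitymap@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the copy numbers of the chemoreceptor
    modification enzymes CheR and CheB shape the run-and-tumble swimming
    phenotype of Escherichia coli. Provides a run-and-tumble trajectory
    simulator driven by CheY-P-controlled flagellar motor switching, a
    three-state Gaussian-mixture classifier for tumble detection, velocity
    autocorrelation and mean-square-displacement estimators of the effective
    diffusion coefficient, a chemotaxis signaling model extended with
    CheB-dependent receptor deamidation, linear-noise-approximation machinery
    for slow methylation fluctuations, correlated lognormal protein-number
    sampling, and local-linear-regression phenotype maps of mean tumble bias
    and its residual variability over (CheR, CheB) copy numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
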