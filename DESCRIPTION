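Package: emtpdl1
Title: Multiscale Modeling of EMT and PD-L1 Crosstalk under Tumor-Mediated
    Immunosuppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of the coupled
    epithelial-mesenchymal transition (EMT) and interferon-gamma-induced
    PD-L1 regulatory network, extended with tumor-mediated suppression of
    IFN-gamma secretion via membrane PD-L1 and via TGF-beta. Provides
    steady-state and bifurcation analysis of the resulting multistable
    system (epithelial, hybrid E/M, and mesenchymal phenotypes), and embeds
    the regulatory network in a two-dimensional multiscale cellular Potts
    model of a T cell-infiltrated tumor with an explicit reaction-diffusion
    IFN-gamma field, a static TGF-beta field, Act-model T cell migration,
    and intratumoral heterogeneity. Includes summary statistics for
    cytokine exposure, phenotype composition, and population-level
    expression curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
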