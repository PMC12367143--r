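Package: aarskinetics
Title: Empirical Kinetic Models of Aminoacyl-tRNA Synthetases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-state kinetic reaction schemes for E. coli class I and
    class II aminoacyl-tRNA synthetases, with exact stochastic (Gillespie)
    and mean-field ODE simulation of the three classical in vitro assays
    (pyrophosphate exchange, single turnover, aminoacylation time course).
    Includes Woolf-Hanes estimation of kcat and Km, exponential fits for
    transfer and chemistry rates, pre-steady-state burst detection, a staged
    parameter-identification procedure, the Michaelis-Menten reduction with
    its kcat/Km rescaling identity, and cellular meta-analysis utilities
    (consensus turnover densities, unit conversions, transcriptome
    reconstruction from RPKM, codon usage, and a steady-state
    charging-demand simulation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
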