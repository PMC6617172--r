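Package: pepcycle
Title: Stochastic Prebiotic Peptide Chemistry and Hypercycle Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A discrete-generation Monte Carlo simulator of prebiotic peptide
    chemistry. Oriented peptides over a six-letter prebiotic amino-acid
    alphabet undergo random pairwise ligation, with acceptance probabilities
    driven by length-dependent interaction coefficients and by a local
    alignment similarity score computed from physico-chemical residue
    coefficients, and random fragmentation proportional to length. Pools are
    periodically reduced by single-linkage clustering of similar sequences
    (epochs), and perturbation protocols (sequence knockouts with paired-seed
    restarts, initial-condition sweeps) report the operational signatures of
    emergent autocatalytic hypercycles, oscillating cluster abundances and
    co-extinction after a knockout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
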