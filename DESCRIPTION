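Package: phosphoform
Title: Intact-Protein Phospho-Stoichiometry, Site Kinetics and Phosphosite Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping multi-site tyrosine phosphorylation of a protein
    that is both a kinase substrate and its own tyrosine phosphatase. Implements
    charge-state-envelope mass calculus and greedy deconvolution of centroided
    native mass spectra into proteoform ladders (start-Met loss, N-terminal
    acetylation, phosphate counts), quantification of the phospho-stoichiometry
    distribution at a chosen charge state, protein-complex mass assignment, a
    two-phase first-order site occupancy model with a Poisson-binomial bridge
    from site occupancies to intact-molecule phosphate counts, bottom-up
    phosphosite relative quantification (representative peptides, reference
    normalisation, percent-of-maximum) with autodephosphorylation-resistance
    classification and condition-by-residue phosphopattern tables, and
    alignment-column conservation scoring (relative entropy and per-column
    tyrosine frequency). Seeded generators produce every input the pipeline
    consumes, so all stages are testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
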