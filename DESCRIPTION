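Package: epifold
Title: Epistasis in a Coarse-Grained Model of Ligand-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates off-lattice ligand-binding proteins as bead chains
    folding by Langevin dynamics under Morse-type pair potentials scaled by
    a residue contact-energy table, selects reference folds from replica
    ensembles by iterative structural alignment, docks a single-monomer
    ligand by a spherical shell sweep, measures fitness as the fraction of
    replicas whose binding complex matches a target geometry, and quantifies
    pairwise epistasis of mutations as the deviation of the double-mutant
    fitness change from additivity. Includes mutation proposal rules
    compatible with the genetic code, a configurable selection loop,
    distribution summaries with a binomial error model, multi-model PDB
    input/output, fixture generators for fast end-to-end runs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
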