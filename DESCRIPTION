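Package: crossbeta
Title: Design and Coarse-Grained Simulation of Parallel Beta-Sheet
    Peptide Nanofibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing short peptides that self-assemble into
    parallel beta-sheet (Class-1 cross-beta spine) nanofibrils. Builds
    idealized two-layer cross-beta backbone scaffolds, runs Monte Carlo
    sequence design with a combined binding/aggregation score, simulates
    multi-chain aggregation with event-driven discontinuous molecular
    dynamics of a four-bead-per-residue coarse-grained peptide model,
    quantifies beta-sheet content and parallel/antiparallel strand
    organization in trajectories, and classifies amide-I FTIR spectra by
    the beta-index criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    igraph,
    signal,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
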