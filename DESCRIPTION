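Package: cpdesign
Title: Physics-Based Fixed-Backbone Protein Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-backbone computational protein design with a
    molecular-mechanics plus Generalized Born plus surface-area folded-state
    energy function. Supports two solvation treatments (a frozen
    native-environment approximation that makes the energy exactly
    pairwise-decomposable, and a fluctuating dielectric boundary that
    recomputes Born radii for every state), an extended-peptide
    unfolded-state model with type-dependent chemical potentials, Metropolis
    Monte Carlo exploration of sequence-rotamer space with a low-energy
    sequence archive, a multi-stage empirical candidate-filtering cascade
    (isoelectric point, fold recognition, BLOSUM similarity, buried
    cavities, net charge, drastic mutations), and thermal-shift analysis of
    differential scanning fluorimetry melt curves. Includes seeded
    generators for every input (ideal-geometry mini-protein scaffolds,
    reference alignments, fold-recognition score tables, melt curves) so
    the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
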