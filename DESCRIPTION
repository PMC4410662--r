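Package: anmkit
Title: Anisotropic Network Models for Proteins, Nucleic Acids and Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds coarse-grained anisotropic elastic network models over
    macromolecular structures read from PDB files, with atom-type-specific
    interaction ranges so the pairwise spring cutoff is the sum t_i + t_j of
    per-type half-ranges. Proteins are reduced to one node per residue
    (C-alpha by default), nucleotides to three nodes (P, C4', C2) and ligand
    heavy atoms to one node each. Computes low-frequency normal modes of the
    network Hessian by dense or sparse shift-invert eigendecomposition, and
    derives the standard fluctuation observables: mean-square fluctuations
    and theoretical B-factors, anisotropic displacement tensors written as
    PDB ANISOU records, cross-correlation and distance-fluctuation maps, and
    multi-frame XYZ mode animations. Includes deterministic toy-structure
    generators so the whole pipeline is testable offline, and a command-line
    driver for one-shot end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    bio3d,
    optparse,
    jsonlite
Config/testthat/edition: 3
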