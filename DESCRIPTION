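Package: flexcmp
Title: Elastic-Network Normal Mode Analysis and Comparative Protein Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained normal mode analysis of protein structures using a
    C-alpha elastic network model with a distance-dependent force constant.
    Computes normalised atomic fluctuation and deformation-energy profiles,
    inter-residue correlation matrices with molecular-viewer export, and the
    overlap of normal modes with an observed conformational change. For sets
    of aligned homologous structures it reduces each Hessian to the
    alignment-conserved residues by a Schur complement and compares the
    resulting dynamics pairwise with the Root Mean Squared Inner Product and
    the Bhattacharyya coefficient, with complete-linkage clustering of the
    similarity matrices. Includes seeded generators for synthetic test
    structures, families and conformational pairs, and a command-line
    interface mirroring the single and comparative analysis tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    MASS,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
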