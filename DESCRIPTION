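Package: combitet
Title: Combinatorial Tetramer Mass Cytometry Screening and Phenotyping
Version: 0.1.0
Authors@R: person("combitet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of mass-cytometry (CyTOF) screens that
    identify antigen-specific CD8+ T cells by combinatorial triple-metal
    peptide-MHC tetramer staining. Provides 3-of-9 tetramer code books and
    2-of-6 palladium sample barcoding, a ground-truth event-level simulator
    of multi-tissue experiments under checkpoint-blockade treatment effects,
    bead-based signal normalization, zero randomization, automated barcode
    deconvolution, sequential gating to live CD8+ T cells, automated
    triple-tetramer decoding with frequency-based hit calling, logicle
    transformation, Barnes-Hut t-SNE phenotype maps with k-means and
    rule-based cluster annotation, and marker-level differential statistics
    (pooled t tests with Holm-Sidak adjustment, Benjamini-Hochberg FDR,
    Fisher's exact test, z-score heat plot matrices). FCS 3.0/3.1 files and
    CSV event tables are supported as interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
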