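Package: neoepitopes
Title: Neoantigen Prioritization from Annotated Somatic Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-guided prioritization of candidate tumor neoantigens from
    annotated missense somatic variants. Builds paired wild-type/mutant peptide
    windows centered on each mutation, obtains per-epitope MHC class I binding
    affinities through a pluggable predictor interface (deterministic built-in
    mock predictor, or a parser for external prediction output), and filters and
    ranks candidate neoepitopes by binding strength (IC50 < 500 nM), mutant
    localization, wild-type versus mutant comparison, sequencing depth, variant
    allele fraction, and gene expression (FPKM). Also provides an auditable
    rule engine for three post-calling somatic variant filter sets, and a
    synthetic fixture generator so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
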