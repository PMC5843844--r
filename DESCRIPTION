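Package: ighdoe
Title: Factorial Optimisation of Memory B Cell Stimulation and Barcoded
    IgH Repertoire Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimising memory B cell expansion cultures by full
    factorial design of experiments (balanced N-way ANOVA variance
    decomposition, first- and second-order sensitivity indices, optimal
    condition selection) and for processing barcoded immunoglobulin
    heavy-chain (IgH) amplicon sequencing libraries (paired-read merging,
    quality and barcode filtering, isotype assignment by constant-region
    k-mer matching, per-molecule consensus building, simplified V/J
    annotation, somatic hypermutation and CDRH3 summaries). A synthetic-data
    module generates paired FASTQ reads with a full ground-truth ledger and
    factorial response tables with known effects, so every stage is testable
    without access-controlled donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
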