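Package: rnaforge
Title: De Novo Transcriptome Assembly from Short RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A de novo transcriptome assembler for paired-end short-read
    RNA-seq built around a bidirected condensed de Bruijn graph. Implements
    RNA-specific graph simplification (conservative tip clipping, length-aware
    bulge collapsing, topology-based removal of chimeric loops and hairpins,
    isolated-edge filtering), two-pass iterative assembly with read-length
    driven k-mer selection and paired-read gap closing, isoform-aware path
    extension with coverage- and strand-based repeat resolution, and tiered
    output filtration. Ships a ground-truthed transcriptome and read simulator
    covering alternative splicing, strand-specific protocols and chimeric
    read artifacts, and an alignment-based evaluator reporting assembled
    isoform fractions, database coverage, duplication ratio and misassemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
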