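Package: txforge
Title: Ontology-Driven Data Integration for De Novo Transcriptome Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A headless toolkit that integrates the downstream results of a
    de novo RNA-seq project (assembled transcripts, structural and functional
    annotation, BLAST alignments, SSR and SNP markers, replicate-structured
    expression values) into a Chado-inspired modular relational store and
    answers combined queries over them. Controlled vocabularies are loaded
    from OBO flat files into ontology DAGs supporting ancestor closure,
    direct/inherited annotation propagation and term-count summaries with
    multiple-annotation semantics. Loaders for FASTA, GFF3, NCBI BLAST XML,
    Blast2GO ANNOT, InterProScan TSV, VCF markers and generic association
    tables all write through typed store operations; expression summaries
    report RPKM with replicate means and standard deviations. A deterministic
    synthetic-project generator and a thin command-line interface replay the
    full tutorial workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    xml2,
    withr,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
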