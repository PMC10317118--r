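Package: strpanel
Title: Short Tandem Repeat Mutator Phenotypes and QTL Mapping in Recombinant
    Inbred Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery of new germline short tandem repeat (STR) mutations in
    two-founder recombinant inbred (RI) panels, summarisation into per-strain
    mutator phenotypes, and quantitative trait locus (QTL) mapping of those
    phenotypes with a linear mixed model and leave-one-chromosome-out kinship.
    Includes founder haplotype-block inference from SNP labels via a two-state
    hidden Markov model, modal-allele inference of missing founder STR
    genotypes, recurrence and per-strain mutation filters, mutation-sharing
    principal component analysis, mutation-spectrum summaries stratified by
    repeat length, motif and haplotype, and a fully synthetic RI-panel
    generator (breeding with recombination and sib-mating inbreeding, and a
    length-dependent stepwise STR mutation process with a genotype-controlled
    expansion bias) so that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    Rcpp,
    vcfR,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
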