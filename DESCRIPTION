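Package: genomesurvey
Title: Desk-Scale Genome Survey Statistics from Shotgun Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Survey-scale computational genomics for large plant genomes:
    k-mer histogram based genome-size estimation (lower and upper bounds from
    the error trough and coverage mode of a canonical k-mer multiplicity
    histogram), average telomere length estimation from shotgun short reads by
    tandem-motif counting, rule cascades for triaging chloroplast reads and
    mitochondrial candidate contigs from alignment and coverage evidence,
    consensus-accuracy estimation from read pileups, ploidy normalization of
    gene counts, and a seeded synthetic-data generator (genomes with telomeric
    arrays, uniform shotgun reads, organelle mixtures, alignments, pileups)
    that provides ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
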