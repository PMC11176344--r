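Package: cngscreen
Title: Genome-Wide Screening of Unstable CNG Trinucleotide Repeat Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heuristic screening pipeline for unstable CNG trinucleotide
    repeat loci: exact maximal tandem-repeat detection in reference genome
    FASTA, gene-model based functional region annotation with explicit
    precedence rules, length-group categorization and candidate selection
    (repeat length and CDS/UTR location), and population repeat-variability
    analytics (allele summary statistics, observed heterozygosity, stability
    classification, exact Wilcoxon cohort comparison). Includes a seeded
    synthetic-data generator (genomes with planted repeat runs, gene models
    with known truth labels, diploid cohorts under random mating) so every
    stage is testable offline, plus report writers and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
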