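# Region annotation: per-transcript rules, precedence resolution,
# strand-awareness, dialect handling and the totality/permutation
# invariants.

test_that("per-transcript classification covers the rule table", {
  m <- toy_coding_model()
  cls <- function(s, e) classify_against_transcript(s, e, "chr1", m, "TX1")
  expect_equal(cls(160, 190), "Coding")          # inside CDS, exon 1
  expect_equal(cls(110, 140), "5'UTR")           # exonic, before CDS
  expect_equal(cls(560, 590), "3'UTR")           # exonic, after CDS
  expect_equal(cls(220, 280), "Intronic")        # intron 1, away from edges
  expect_equal(cls(190, 210), "Exonic;Splicing") # CDS + first intron bases
  expect_equal(cls(202, 250), "Intronic")        # past the 2 bp splice window
  expect_equal(cls(250, 299), "Splicing")        # acceptor side, intron only
  expect_equal(cls(140, 160), "Coding")          # UTR+CDS resolves to Coding
  # flanks: gap to span, 0 = adjacent
  expect_true(is.na(cls(2000, 2030)))
  expect_equal(cls(50, 90), "Upstream")
  expect_equal(cls(700, 730), "Downstream")
  expect_true(is.na(classify_against_transcript(160, 190, "chr2", m, "TX1")))
  # window boundary: 1 kb window reaches gaps of at most 999 bases
  expect_equal(classify_against_transcript(1600, 1620, "chr1", m, "TX1"),
               NA_character_)
  expect_equal(classify_against_transcript(1599, 1620, "chr1", m, "TX1"),
               "Downstream")
})

test_that("strand flips UTR sides and flank directions", {
  m <- toy_coding_model(strand = "-")
  cls <- function(s, e) classify_against_transcript(s, e, "chr1", m, "TX1")
  expect_equal(cls(110, 140), "3'UTR")
  expect_equal(cls(560, 590), "5'UTR")
  expect_equal(cls(50, 90), "Downstream")
  expect_equal(cls(700, 730), "Upstream")
})

test_that("noncoding transcripts yield ncRNA labels", {
  m <- toy_noncoding_model()
  cls <- function(s, e) classify_against_transcript(s, e, "chr1", m, "NC1")
  expect_equal(cls(1020, 1050), "ncRNA-Exonic")
  expect_equal(cls(1150, 1250), "ncRNA-Intronic")
})

test_that("precedence resolves multi-transcript conflicts upward", {
  # transcript A: locus in 5'UTR; transcript B overlapping: locus in CDS
  txs <- data.frame(
    tx_id = c("A", "B"), gene = c("GA", "GB"), chrom = "chr1",
    strand = "+", tx_start = c(100L, 50L), tx_end = c(600L, 700L),
    cds_start = c(400L, 60L), cds_end = c(550L, 650L), coding = TRUE,
    stringsAsFactors = FALSE)
  ex <- data.frame(tx_id = c("A", "B"),
                   start = c(100L, 50L), end = c(600L, 700L),
                   stringsAsFactors = FALSE)
  m <- gene_model(txs, ex)
  ann <- annotate_loci(locus_row(150, 180), m)
  expect_equal(ann$label, "Coding")
  expect_equal(ann$gene, "GB")

  # adding a transcript can only move the label up in precedence
  mA <- gene_model(txs[1, ], ex[1, ])
  annA <- annotate_loci(locus_row(150, 180), mA)
  prec <- region_precedence()
  expect_lte(match(ann$label, prec), match(annA$label, prec))
})

test_that("combined flanking and UTR labels arise from transcript pairs", {
  # Upstream of one transcript and Downstream of another
  txs <- data.frame(
    tx_id = c("L", "R"), gene = c("GL", "GR"), chrom = "chr1", strand = "+",
    tx_start = c(1000L, 3000L), tx_end = c(1500L, 3500L),
    cds_start = c(1100L, 3100L), cds_end = c(1400L, 3400L), coding = TRUE,
    stringsAsFactors = FALSE)
  ex <- data.frame(tx_id = c("L", "R"), start = c(1000L, 3000L),
                   end = c(1500L, 3500L), stringsAsFactors = FALSE)
  m <- gene_model(txs, ex)
  ann <- annotate_loci(locus_row(2200, 2230), m)
  expect_equal(ann$label, "Upstream/Downstream")
  expect_equal(ann$gene, "GR")   # attributed to the upstream transcript

  # 5'UTR of one and 3'UTR of the other
  txs2 <- txs
  txs2$tx_start <- c(100L, 80L); txs2$tx_end <- c(600L, 320L)
  txs2$cds_start <- c(400L, 100L); txs2$cds_end <- c(550L, 250L)
  ex2 <- data.frame(tx_id = c("L", "R"), start = c(100L, 80L),
                    end = c(600L, 320L), stringsAsFactors = FALSE)
  m2 <- gene_model(txs2, ex2)
  ann2 <- annotate_loci(locus_row(260, 300), m2)
  expect_equal(ann2$label, "5'UTR;3'UTR")
})

test_that("every locus gets exactly one label; unknown chrom is intergenic", {
  m <- toy_coding_model()
  loci <- rbind(locus_row(160, 190), locus_row(5, 20, chrom = "chrZ"))
  expect_warning(ann <- annotate_loci(loci, m), "chrZ")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$label, c("Coding", "Intergenic"))
  expect_equal(ann$gene, c("G1", ""))
  expect_error(annotate_loci(loci, m, unknown_chrom = "error"), "chrZ")
})

test_that("transcript input order never changes labels", {
  set.seed(99)
  specs <- data.frame(chrom = "chr1",
                      position = c(5000, 12000, 20000, 28000),
                      unit = "CAG", n_units = 10,
                      label_truth = c("Coding", "5'UTR", "Intronic",
                                      "Upstream"))
  g <- make_genome(specs, c(chr1 = 40000), seed = 5)
  gm <- make_gene_model(g$truth)
  loci <- g$expected
  base <- annotate_loci(loci, gm$model)
  for (i in 1:5) {
    perm <- sample(nrow(gm$model$transcripts))
    m2 <- gene_model(gm$model$transcripts[perm, ], gm$model$exons)
    expect_equal(annotate_loci(loci, m2)$label, base$label)
  }
})

test_that("GFF3 and refGene dialects produce identical annotations", {
  specs <- data.frame(chrom = "chr1",
                      position = c(5000, 12000, 20000, 28000, 36000),
                      unit = "CAG", n_units = 10,
                      label_truth = c("Coding", "5'UTR", "3'UTR",
                                      "ncRNA-Exonic", "Intronic"),
                      strand = c("+", "-", "+", "+", "-"))
  g <- make_genome(specs, c(chr1 = 50000), seed = 21)
  gm <- make_gene_model(g$truth)
  gff <- tempfile(fileext = ".gff3"); rg <- tempfile(fileext = ".tsv")
  write_gene_model(gm, gff)
  write_refgene(gm$model, rg)
  m_gff <- read_gene_model(gff, quiet = TRUE)
  m_rg <- read_gene_model(rg, quiet = TRUE)
  a1 <- annotate_loci(g$expected, m_gff)
  a2 <- annotate_loci(g$expected, m_rg)
  expect_equal(a1$label, a2$label)
  expect_equal(a1$label, g$truth$label_truth)
  # dialect detection is logged
  expect_message(read_gene_model(gff), "GFF3")
  expect_message(read_gene_model(rg), "refGene")
})
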