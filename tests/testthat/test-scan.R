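# Maximal exact repeat detection: worked micro-examples, error contract,
# and the maximality / reconstruction / strand-symmetry properties.

test_that("worked micro-examples give the forced maximal runs", {
  cfg <- scan_config("CAG")
  expect_equal(nrow(scan_sequence("", "c", cfg)), 0L)

  one <- scan_sequence("TTCAGCAGCAGCAGAA", "c", cfg)
  expect_equal(one$start0, 2L)
  expect_equal(one$end0, 14L)
  expect_equal(one$n_units, 4L)

  expect_equal(nrow(scan_sequence("CAGCAGCAG", "c", cfg)), 0L)

  # partial trailing copies never count
  expect_equal(nrow(scan_sequence("CAGCAGCA", "c", scan_config("CAG", 2))), 1L)
  expect_equal(scan_sequence("CAGCAGCA", "c", scan_config("CAG", 2))$n_units, 2L)

  # frame-shifted overlap: a CCG run contains a one-unit-shorter GCC run
  two <- scan_sequence(strrep("CCG", 6), "c", scan_config(c("CCG", "GCC")))
  expect_equal(two$unit, c("CCG", "GCC"))
  expect_equal(two$start0, c(0L, 2L))
  expect_equal(two$n_units, c(6L, 5L))
})

test_that("ambiguous bases split runs; the flanks are judged separately", {
  cfg <- scan_config("CAG")
  res <- scan_sequence("CAGCAGNCAGCAGCAGCAG", "c", cfg)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start0, 7L)
  expect_equal(res$n_units, 4L)

  # IUPAC codes other than N also break runs
  res2 <- scan_sequence("CAGCAGCAGCAGRCAGCAGCAGCAG", "c", cfg)
  expect_equal(res2$n_units, c(4L, 4L))

  # wildcard mode bridges the N
  cfgw <- scan_config("CAG", break_on_ambiguous = FALSE)
  resw <- scan_sequence("CAGCAGCAGNAGCAG", "c", cfgw)
  expect_equal(resw$n_units, 5L)
})

test_that("invalid input is rejected with the offending position", {
  expect_error(scan_sequence("CAGXCAG", "c", scan_config("CAG")),
               "position 4")
  expect_error(scan_config(character()), "non-empty")
  expect_error(scan_config(c("CAG", "CAG")), "duplicate")
  expect_error(scan_config("CAG", min_units = 1), ">= 2")
  expect_error(repeat_motif("CAX"), "outside")
  expect_error(repeat_motif(""), "non-empty")
  expect_error(repeat_motif("AAA"), "shorter unit")
})

test_that("case-insensitive scanning treats soft-masked sequence as sequence", {
  cfg <- scan_config("CAG")
  s <- "ttCAGcagCAGcagAA"
  a <- scan_sequence(s, "c", cfg)
  b <- scan_sequence(toupper(s), "c", cfg)
  expect_equal(a[, c("start0", "end0", "unit", "n_units")],
               b[, c("start0", "end0", "unit", "n_units")])
  expect_equal(a$n_units, 4L)
  # case-sensitive: lowercase does not match
  expect_equal(nrow(scan_sequence(s, "c", scan_config("CAG",
                                                      case_sensitive = TRUE))),
               0L)
})

test_that("reported runs are maximal and reconstruct the substring", {
  set.seed(42)
  cfg <- scan_config()
  for (rep in 1:20) {
    seq <- paste0(random_dna(150), strrep("CAG", sample(4:9, 1)),
                  random_dna(150))
    res <- scan_sequence(seq, "c", cfg)
    for (i in seq_len(nrow(res))) {
      u <- res$unit[i]; L <- nchar(u)
      s <- res$start0[i]; e <- res$end0[i]
      expect_identical(toupper(substring(seq, s + 1, e)),
                       strrep(u, res$n_units[i]))
      expect_equal(e - s, res$n_units[i] * L)
      # no full copy immediately before or after
      if (s - L >= 0) {
        expect_false(toupper(substring(seq, s - L + 1, s)) == u)
      }
      if (e + L <= nchar(seq)) {
        expect_false(toupper(substring(seq, e + 1, e + L)) == u)
      }
    }
  }
})

test_that("motif counts mirror under reverse complement", {
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(7)
  for (rep in 1:10) {
    seq <- paste0(random_dna(100), strrep("CAG", 5), random_dna(50),
                  strrep("CCG", 6), random_dna(100))
    fwd <- scan_sequence(seq, "c", scan_config("CAG"))
    rev <- scan_sequence(revcomp(seq), "c", scan_config("CTG"))
    expect_equal(nrow(fwd), nrow(rev))
    # mirrored coordinates
    n <- nchar(seq)
    expect_setequal(paste(n - fwd$end0, n - fwd$start0),
                    paste(rev$start0, rev$end0))
  }
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(1234)
  cfg <- scan_config(min_units = 3L)
  for (rep in 1:60) {
    # repeat-enriched alphabet so runs actually occur
    seq <- random_dna(300, alphabet = c("A", "C", "G", "T", "C", "G"))
    a <- scan_sequence(seq, "seq", cfg)
    b <- brute_force_oracle(seq, cfg)
    expect_equal(a, b, info = paste("seed rep", rep))
  }
  expect_error(brute_force_oracle(random_dna(200), guard = 100),
               "guard")
})

test_that("frame-shift dedup suppresses contained rotational duplicates", {
  seq <- strrep("CCG", 6)
  keep <- scan_sequence(seq, "c", scan_config(c("CCG", "GCC"),
                                              dedup_frame_shifts = TRUE))
  expect_equal(keep$unit, "CCG")
  # non-rotational overlaps are untouched
  both <- scan_sequence(seq, "c", scan_config(c("CCG", "GCC")))
  expect_equal(nrow(both), 2L)
})

test_that("scan_fasta streams records in order and rejects bad files", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">rec1", strrep("CAG", 10), ">rec2", strrep("CAG", 10)), fa)
  res <- scan_fasta(fa, scan_config("CAG"), quiet = TRUE)
  expect_equal(res$chrom, c("rec1", "rec2"))
  expect_equal(res$n_units, c(10L, 10L))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">r", "ACGT", ">r", "ACGT"), dup)
  expect_error(scan_fasta(dup, quiet = TRUE), "duplicate")
  expect_error(scan_fasta(tempfile(), quiet = TRUE), "not found")
})

test_that("locus writer emits both coordinate dialects and BED", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1", paste0("TT", strrep("CAG", 5))), fa)
  loci <- scan_fasta(fa, scan_config("CAG"), quiet = TRUE)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_locus_table(loci, tsv, bed_path = bed)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(tab$start1, tab$start0 + 1L)
  expect_equal(tab$end1, tab$end0)
  bedtab <- read.table(bed, sep = "\t")
  expect_equal(bedtab$V2, loci$start0)
  expect_equal(bedtab$V4, "CAG:5")
})
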