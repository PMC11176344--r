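# Fragment conversion, allele-distribution summaries, stability calls,
# and the external catalog loader.

test_that("fragment sizes convert to repeat units with residual warning", {
  expect_equal(fragment_to_units(100, 70, 3), 10L)
  k <- 1:12
  expect_equal(fragment_to_units(70 + 3 * k, 70, 3), k)
  expect_warning(u <- fragment_to_units(101.4, 70, 3), "off")
  expect_equal(u, 10L)
  expect_error(fragment_to_units(60, 70), "exceed")
})

test_that("locus summary matches hand computation over the allele multiset", {
  calls <- data.frame(sample = paste0("S", 1:4), locus = "L1",
                      a1 = c(10, 12, 10, 10), a2 = c(12, 12, 10, 12))
  s <- locus_summary(calls)
  expect_equal(s$hi, 0.5)
  expect_equal(s$mode, 10)       # 4 vs 4 tie breaks toward the smaller
  expect_equal(s$mean, 11)
  expect_equal(s$median, 11)
  expect_equal(s$n_chromosomes, 8L)
  expect_equal(s$n_alleles, 2L)

  mono <- data.frame(sample = paste0("S", 1:10), locus = "L",
                     a1 = 12, a2 = 12)
  sm <- locus_summary(mono)
  expect_equal(c(sm$min, sm$max, sm$n_alleles, sm$hi, sm$mean, sm$sd),
               c(12, 12, 1, 0, 12, 0))

  one <- locus_summary(data.frame(sample = "S1", locus = "L",
                                  a1 = 10, a2 = 14))
  expect_equal(one$hi, 1)
  expect_equal(c(one$min, one$max), c(10, 14))
  expect_error(locus_summary(calls[0, ]), "no calls")
})

test_that("summaries are invariant to sample order and allele swaps", {
  set.seed(3)
  calls <- data.frame(sample = paste0("S", 1:30), locus = "L",
                      a1 = sample(8:15, 30, TRUE),
                      a2 = sample(8:15, 30, TRUE))
  base <- locus_summary(calls)
  perm <- calls[sample(nrow(calls)), ]
  expect_equal(locus_summary(perm), base)
  swapped <- calls
  swapped$a1 <- calls$a2; swapped$a2 <- calls$a1
  expect_equal(locus_summary(swapped), base)
})

test_that("HI is 0 iff no heterozygote and 1 iff all heterozygous", {
  het <- data.frame(sample = paste0("S", 1:5), locus = "L",
                    a1 = 10, a2 = 11)
  expect_equal(locus_summary(het)$hi, 1)
  hom <- data.frame(sample = paste0("S", 1:5), locus = "L",
                    a1 = c(10, 11, 12, 10, 11), a2 = c(10, 11, 12, 10, 11))
  expect_equal(locus_summary(hom)$hi, 0)
})

test_that("stability classification uses the span rule and is monotone", {
  expect_equal(classify_stability(18, 23), "stable")        # span 5
  expect_equal(classify_stability(6, 29), "polymorphic")    # span 23
  expect_equal(classify_stability(12, 12), "stable")        # span 0
  expect_equal(classify_stability(10, 17), "polymorphic")   # span 7 boundary
  expect_equal(classify_stability(10, 16), "stable")        # span 6
  # widening the range can never flip polymorphic -> stable
  set.seed(11)
  for (i in 1:50) {
    lo <- sample(5:20, 1); hi <- lo + sample(0:20, 1)
    cls <- classify_stability(lo, hi)
    wider <- classify_stability(lo - 1, hi + 1)
    if (cls == "polymorphic") expect_equal(wider, "polymorphic")
  }
  # override forces named loci polymorphic
  expect_equal(classify_stability(11, 17, locus = "RAI1",
                                  override_polymorphic = "RAI1"),
               "polymorphic")
  expect_error(classify_stability(17, 11), "max < min")
})

test_that("cohort summarization rejects duplicate calls and groups by locus", {
  calls <- data.frame(sample = rep(paste0("S", 1:3), 2),
                      locus = rep(c("A", "B"), each = 3),
                      a1 = c(10, 10, 10, 5, 5, 20),
                      a2 = c(10, 10, 11, 5, 6, 5))
  s <- summarize_cohort(calls)
  expect_equal(s$locus, c("A", "B"))
  expect_equal(s$stability, c("stable", "polymorphic"))
  dup <- rbind(calls, calls[1, ])
  expect_error(summarize_cohort(dup), "more than one call")
})

test_that("calls reader handles both layouts and flank conversion", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = c("S1", "S2"), cohort = "ctrl",
                         locus = "L1", a1_units = c(12, 10),
                         a2_units = c(10, 10)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- read_calls(p)
  expect_equal(calls$a1, c(10L, 10L))   # normalized a1 <= a2
  expect_equal(calls$a2, c(12L, 10L))

  pf <- tempfile(fileext = ".tsv"); pc <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = "S1", cohort = "ctrl", locus = "L1",
                         frag1_bp = 100, frag2_bp = 106),
              pf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(locus = "L1", flank_bp = 70, unit_len = 3),
              pc, sep = "\t", quote = FALSE, row.names = FALSE)
  calls2 <- read_calls(pf, locus_config = pc)
  expect_equal(c(calls2$a1, calls2$a2), c(10L, 12L))
  expect_error(read_calls(pf), "locus_config")
})

test_that("external catalog loads, reports and rejects malformed rows", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("population\tlocus\tallele_units\tcount",
               "AFR\tGLS\t12\t10",
               "AFR\tGLS\t14\t10",
               "EUR\tGLS\t14\t5"), p)
  cat <- load_external_catalog(p)
  rep <- catalog_report(cat)
  expect_equal(rep$display[rep$population == "AFR"], "12 (12-14)") # tie -> smaller
  expect_equal(rep$display[rep$population == "EUR"], "14 (14-14)")
  expect_equal(catalog_alleles(cat, "AFR", "GLS"), rep(c(12L, 14L), c(10, 10)))

  bad <- tempfile(); writeLines(c("population\tlocus\tallele_units\tcount",
                                  "AFR\tGLS\ttwelve\t10"), bad)
  expect_error(load_external_catalog(bad), "line 2")
  empty <- tempfile(); writeLines(character(), empty)
  expect_warning(e <- load_external_catalog(empty), "empty")
  expect_equal(nrow(e), 0L)
})
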