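# Seeded synthetic fixtures with known truth: genomes with planted repeat
# runs, gene models that place each planted run in a requested region,
# and diploid cohorts drawn from specified allele-frequency spectra.

# A flanking base guaranteed to break any run or rotation of `unit`.
breaker_base <- function(unit) {
  chars <- strsplit(unit, "")[[1]]
  cand <- setdiff(c("T", "A", "C", "G"), chars)
  if (!length(cand)) stop("unit uses all four bases; cannot pick a breaker",
                          call. = FALSE)
  cand[1]
}

#' Build a synthetic genome with planted repeat runs
#'
#' Plants exact maximal repeat runs at requested positions on random
#' background sequence. Each planted run is flanked by unit-length blocks
#' of a base absent from the motif, so it can never be extended and no
#' rotation of it can leak into the background. Background sequence is
#' rejection-sampled: any accidental run of a configured motif reaching
#' `config$min_units` outside the planted regions is redrawn, so the
#' returned truth table is exhaustive for the configured scan.
#'
#' A planted run of a motif also contains runs of that motif's rotations
#' (one unit shorter); where such a rotation is itself in the configured
#' motif set, the derived run is part of the expected scan output and is
#' listed in `$expected` with `planted = FALSE`.
#'
#' @param specs Data.frame with columns `chrom`, `position` (0-based
#'   start), `unit`, `n_units`; optional `label_truth` (a region label
#'   consumed by [make_gene_model()]) and `strand`.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @param config [scan_config()] defining the motif set and minimum run
#'   length that the truth table must be exhaustive for.
#' @return List of class `"synthetic_genome"`: `$sequences` (named
#'   character vector), `$truth` (planted loci), `$expected` (full
#'   expected scan output for `config`: planted + derived rotation runs,
#'   sorted like [scan_sequence()] output), `$seed`, `$config`.
#' @export
make_genome <- function(specs, chrom_lengths, seed, config = scan_config()) {
  stopifnot(is.data.frame(specs))
  if (nrow(specs)) {
    specs$unit <- vapply(specs$unit, repeat_motif, character(1))
    specs$position <- as.integer(specs$position)
    specs$n_units <- as.integer(specs$n_units)
    if (any(specs$n_units < 1L)) stop("n_units must be >= 1", call. = FALSE)
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  set.seed(seed)

  ulen <- if (nrow(specs)) nchar(specs$unit) else integer()
  start0 <- specs$position
  end0 <- start0 + specs$n_units * ulen
  # reserved = run plus unit-length breaker flank on each side
  res_start <- start0 - ulen
  res_end <- end0 + ulen
  for (i in seq_len(nrow(specs))) {
    ch <- specs$chrom[i]
    if (!ch %in% names(chrom_lengths)) {
      stop("spec chromosome not in chrom_lengths: ", ch, call. = FALSE)
    }
    if (res_start[i] < 0L || res_end[i] > chrom_lengths[[ch]]) {
      stop("planted run (with flanks) outside chromosome ", ch,
           " at row ", i, call. = FALSE)
    }
    same <- which(specs$chrom == ch)
    for (j in same) {
      if (j == i) next
      gap_ok <- end0[i] + ulen[i] + ulen[j] <= start0[j] ||
        end0[j] + ulen[i] + ulen[j] <= start0[i]
      if (!gap_ok) {
        stop("planted runs too close on ", ch, " (rows ", min(i, j), ", ",
             max(i, j), "): need >= 2 unit lengths of separation",
             call. = FALSE)
      }
    }
  }

  sequences <- character(0)
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    rows <- which(specs$chrom == ch)
    protected <- logical(len)   # planted runs + breaker flanks, never redrawn
    for (i in rows) {
      b <- breaker_base(specs$unit[i])
      bases[(res_start[i] + 1L):(start0[i])] <- b
      bases[(start0[i] + 1L):(end0[i])] <-
        strsplit(strrep(specs$unit[i], specs$n_units[i]), "")[[1]]
      bases[(end0[i] + 1L):(res_end[i])] <- b
      protected[(res_start[i] + 1L):(res_end[i])] <- TRUE
    }
    expected_ch <- expected_for_chrom(specs[rows, , drop = FALSE], config)
    key <- function(df) paste(df$start0, df$end0, df$unit)
    for (iter in 1:100) {
      found <- scan_sequence(paste(bases, collapse = ""), ch, config)
      extra <- found[!key(found) %in% key(expected_ch), , drop = FALSE]
      if (!nrow(extra)) break
      if (iter == 100L) {
        stop("rejection sampling failed to clear accidental runs on ", ch,
             call. = FALSE)
      }
      for (k in seq_len(nrow(extra))) {
        pos <- (extra$start0[k] + 1L):(extra$end0[k])
        pos <- pos[!protected[pos]]
        if (!length(pos)) {
          stop("accidental run inside a protected region on ", ch,
               " — unsatisfiable spec", call. = FALSE)
        }
        bases[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      }
    }
    missing <- expected_ch[!key(expected_ch) %in% key(found), , drop = FALSE]
    if (nrow(missing)) {
      stop("planted run not recovered on ", ch, " — internal error",
           call. = FALSE)
    }
    sequences[[ch]] <- paste(bases, collapse = "")
  }

  truth <- if (nrow(specs)) {
    data.frame(chrom = specs$chrom, start0 = start0, end0 = end0,
               unit = specs$unit, n_units = specs$n_units,
               label_truth = if ("label_truth" %in% names(specs))
                 specs$label_truth else NA_character_,
               strand = if ("strand" %in% names(specs))
                 specs$strand else "+",
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start0 = integer(), end0 = integer(),
               unit = character(), n_units = integer(),
               label_truth = character(), strand = character(),
               stringsAsFactors = FALSE)
  }
  expected <- do.call(rbind, c(
    lapply(names(chrom_lengths), function(ch) {
      expected_for_chrom(specs[specs$chrom == ch, , drop = FALSE], config)
    }),
    list(data.frame(chrom = character(), start0 = integer(),
                    end0 = integer(), unit = character(),
                    n_units = integer(), planted = logical(),
                    stringsAsFactors = FALSE))))
  expected <- expected[order(expected$chrom, expected$start0, expected$unit), ]
  rownames(expected) <- NULL
  structure(list(sequences = sequences, truth = truth, expected = expected,
                 seed = seed, config = config),
            class = "synthetic_genome")
}

# Expected scan output for one chromosome's planted specs under config:
# the planted runs themselves (if long enough and their motif is scanned)
# plus rotation-derived runs one unit shorter.
expected_for_chrom <- function(specs, config) {
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    u <- specs$unit[i]; L <- nchar(u)
    s <- specs$position[i]; n <- specs$n_units[i]
    rot <- motif_rotations(u)
    for (d in seq_along(rot) - 1L) {
      v <- rot[d + 1L]
      nv <- if (d == 0L) n else n - 1L
      if (v %in% config$motifs && nv >= config$min_units) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = specs$chrom[i], start0 = s + d, end0 = s + d + nv * L,
          unit = v, n_units = nv, planted = d == 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(chrom = character(), start0 = integer(), end0 = integer(),
               unit = character(), n_units = integer(), planted = logical(),
               stringsAsFactors = FALSE))))
  if (isTRUE(config$dedup_frame_shifts) && nrow(out) > 1L) {
    out <- dedup_frame_shifted(out)
  }
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome: ", length(x$sequences), " chromosome(s), ",
      nrow(x$truth), " planted run(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic genome to FASTA (+ truth TSV)
#'
#' @param genome A `synthetic_genome` from [make_genome()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional truth TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_genome <- function(genome, fasta_path, truth_path = NULL) {
  dss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dss, fasta_path, width = 60L)
  if (!is.null(truth_path)) write_tsv_atomic(genome$truth, truth_path)
  invisible(fasta_path)
}

# ---- gene model construction -------------------------------------------

# Interval templates (genomic offsets relative to the locus [s, e)) that
# place the locus into each requested region. All coding templates keep
# the CDS inside one exon block; splice windows never touch the locus.
gene_template <- function(label, s, e, strand) {
  minus <- identical(strand, "-")
  switch(label,
    "Coding" = list(tx = c(s - 300L, e + 300L),
                    exons = rbind(c(s - 300L, e + 300L)),
                    cds = c(s - 100L, e + 100L), coding = TRUE),
    "5'UTR" = if (!minus) {
      list(tx = c(s - 200L, e + 400L), exons = rbind(c(s - 200L, e + 400L)),
           cds = c(e + 50L, e + 350L), coding = TRUE)
    } else {
      list(tx = c(s - 400L, e + 200L), exons = rbind(c(s - 400L, e + 200L)),
           cds = c(s - 350L, s - 50L), coding = TRUE)
    },
    "3'UTR" = if (!minus) {
      list(tx = c(s - 400L, e + 200L), exons = rbind(c(s - 400L, e + 200L)),
           cds = c(s - 350L, s - 50L), coding = TRUE)
    } else {
      list(tx = c(s - 200L, e + 400L), exons = rbind(c(s - 200L, e + 400L)),
           cds = c(e + 50L, e + 350L), coding = TRUE)
    },
    "Intronic" = list(tx = c(s - 500L, e + 500L),
                      exons = rbind(c(s - 500L, s - 300L),
                                    c(e + 300L, e + 500L)),
                      cds = c(s - 460L, s - 340L), coding = TRUE),
    "ncRNA-Exonic" = list(tx = c(s - 200L, e + 200L),
                          exons = rbind(c(s - 200L, e + 200L)),
                          cds = NULL, coding = FALSE),
    "ncRNA-Intronic" = list(tx = c(s - 500L, e + 500L),
                            exons = rbind(c(s - 500L, s - 300L),
                                          c(e + 300L, e + 500L)),
                            cds = NULL, coding = FALSE),
    "Upstream" = if (!minus) {
      list(tx = c(e + 500L, e + 2000L), exons = rbind(c(e + 500L, e + 2000L)),
           cds = c(e + 700L, e + 1800L), coding = TRUE)
    } else {
      list(tx = c(s - 2000L, s - 500L), exons = rbind(c(s - 2000L, s - 500L)),
           cds = c(s - 1800L, s - 700L), coding = TRUE)
    },
    "Downstream" = if (!minus) {
      list(tx = c(s - 2000L, s - 500L), exons = rbind(c(s - 2000L, s - 500L)),
           cds = c(s - 1800L, s - 700L), coding = TRUE)
    } else {
      list(tx = c(e + 500L, e + 2000L), exons = rbind(c(e + 500L, e + 2000L)),
           cds = c(e + 700L, e + 1800L), coding = TRUE)
    },
    stop("make_gene_model cannot place label: ", label, call. = FALSE)
  )
}

#' Build a gene model placing planted loci into requested regions
#'
#' For each planted locus whose `label_truth` is a genic label, one
#' transcript (two for `5'UTR;3'UTR`) is constructed so that annotation
#' with the default windows returns exactly that label. `Intergenic` loci
#' get no transcript; the builder verifies that no constructed transcript
#' (plus the upstream window) reaches any other planted locus, so the
#' truth table is exact by construction. Supported labels: Coding, 5'UTR,
#' 3'UTR, 5'UTR;3'UTR, Intronic, ncRNA-Exonic, ncRNA-Intronic, Upstream,
#' Downstream, Intergenic; anything else is rejected.
#'
#' @param truth Planted-locus table from [make_genome()] (`$truth`), with
#'   `label_truth` and optional `strand` columns.
#' @param seed Integer seed (reserved for placement jitter; construction
#'   is deterministic either way).
#' @param upstream_window Window used for the isolation check (default
#'   1000, matching the annotator default).
#' @return List of class `"synthetic_genes"`: `$model` (a `gene_model`),
#'   `$truth` (locus table with expected `label`, `gene`, `transcript`),
#'   `$gff3` (character vector of GFF3 lines).
#' @export
make_gene_model <- function(truth, seed = 1L, upstream_window = 1000L) {
  stopifnot(is.data.frame(truth))
  if (!"label_truth" %in% names(truth)) {
    stop("truth table needs a label_truth column", call. = FALSE)
  }
  if (!"strand" %in% names(truth)) truth$strand <- "+"
  set.seed(seed)

  tx_rows <- list(); ex_rows <- list()
  exp_gene <- character(nrow(truth)); exp_tx <- character(nrow(truth))
  add_tx <- function(id, gene, chrom, tpl) {
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      tx_id = id, gene = gene, chrom = chrom,
      strand = tpl$strand, tx_start = tpl$tx[1], tx_end = tpl$tx[2],
      cds_start = if (tpl$coding) tpl$cds[1] else NA_integer_,
      cds_end = if (tpl$coding) tpl$cds[2] else NA_integer_,
      coding = tpl$coding, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(tpl$exons))) {
      ex_rows[[length(ex_rows) + 1L]] <<- data.frame(
        tx_id = id, start = tpl$exons[r, 1], end = tpl$exons[r, 2],
        stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(nrow(truth))) {
    lab <- truth$label_truth[i]
    if (is.na(lab) || lab == "Intergenic") next
    s <- truth$start0[i]; e <- truth$end0[i]
    strand <- truth$strand[i]
    gene <- sprintf("GENE%03d", i)
    if (lab == "5'UTR;3'UTR") {
      # 5'UTR of transcript A plus 3'UTR of overlapping transcript B
      ta <- gene_template("5'UTR", s, e, strand); ta$strand <- strand
      tb <- gene_template("3'UTR", s, e, strand); tb$strand <- strand
      add_tx(sprintf("TX%03da", i), gene, truth$chrom[i], ta)
      add_tx(sprintf("TX%03db", i), gene, truth$chrom[i], tb)
      exp_gene[i] <- gene; exp_tx[i] <- sprintf("TX%03da", i)
    } else {
      tpl <- gene_template(lab, s, e, strand); tpl$strand <- strand
      id <- sprintf("TX%03d", i)
      add_tx(id, gene, truth$chrom[i], tpl)
      exp_gene[i] <- gene; exp_tx[i] <- id
    }
  }
  transcripts <- do.call(rbind, c(tx_rows, list(data.frame(
    tx_id = character(), gene = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(), coding = logical(),
    stringsAsFactors = FALSE))))
  exons <- do.call(rbind, c(ex_rows, list(data.frame(
    tx_id = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE))))
  if (any(transcripts$tx_start < 0L)) {
    stop("a transcript template extends below position 0; move the locus",
         call. = FALSE)
  }

  # isolation: no transcript (span + window) may reach a *different* locus
  for (j in seq_len(nrow(transcripts))) {
    tx <- transcripts[j, ]
    locus_idx <- as.integer(sub("[ab]?$", "", sub("^TX", "", tx$tx_id)))
    for (i in seq_len(nrow(truth))) {
      if (i == locus_idx) next
      if (truth$chrom[i] == tx$chrom &&
          truth$start0[i] < tx$tx_end + upstream_window &&
          tx$tx_start - upstream_window < truth$end0[i]) {
        stop("transcript for locus ", locus_idx, " reaches planted locus ",
             i, "; space loci further apart", call. = FALSE)
      }
    }
  }

  model <- new_gene_model(transcripts, exons)
  out_truth <- truth
  out_truth$label <- ifelse(is.na(truth$label_truth), "Intergenic",
                            truth$label_truth)
  out_truth$gene <- exp_gene
  out_truth$transcript <- exp_tx
  structure(list(model = model, truth = out_truth,
                 gff3 = gene_model_to_gff3(model)),
            class = "synthetic_genes")
}

#' @export
print.synthetic_genes <- function(x, ...) {
  cat("synthetic_genes: ", nrow(x$model$transcripts), " transcript(s) for ",
      nrow(x$truth), " planted locus/loci\n", sep = "")
  invisible(x)
}

# Serialize a gene_model to GFF3 lines (1-based inclusive).
gene_model_to_gff3 <- function(model) {
  lines <- "##gff-version 3"
  txs <- model$transcripts
  for (j in seq_len(nrow(txs))) {
    tx <- txs[j, ]
    ex <- model$exons[model$exons$tx_id == tx$tx_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    type <- if (tx$coding) "mRNA" else "ncRNA"
    lines <- c(lines, sprintf(
      "%s\tcngscreen\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
      tx$chrom, type, tx$tx_start + 1L, tx$tx_end, tx$strand,
      tx$tx_id, tx$gene))
    for (r in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tcngscreen\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        tx$chrom, ex$start[r] + 1L, ex$end[r], tx$strand, tx$tx_id))
      if (tx$coding) {
        cs <- max(ex$start[r], tx$cds_start); ce <- min(ex$end[r], tx$cds_end)
        if (cs < ce) {
          lines <- c(lines, sprintf(
            "%s\tcngscreen\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
            tx$chrom, cs + 1L, ce, tx$strand, tx$tx_id))
        }
      }
    }
  }
  lines
}

#' Write a synthetic gene model as GFF3 (+ truth TSV)
#'
#' @param genes A `synthetic_genes` from [make_gene_model()].
#' @param gff3_path Output GFF3 path.
#' @param truth_path Optional truth TSV path.
#' @return `gff3_path`, invisibly.
#' @export
write_gene_model <- function(genes, gff3_path, truth_path = NULL) {
  con <- file(gff3_path, open = "wb")
  writeLines(genes$gff3, con)
  close(con)
  if (!is.null(truth_path)) {
    cols <- c("chrom", "start0", "end0", "unit", "label", "gene", "transcript")
    write_tsv_atomic(genes$truth[, cols], truth_path)
  }
  invisible(gff3_path)
}

# ---- cohort simulation --------------------------------------------------

#' Simulate a diploid cohort from allele-frequency spectra
#'
#' Draws, for every sample and locus, two alleles independently from the
#' locus spectrum (Hardy-Weinberg random mating). Deterministic per seed.
#'
#' @param spectra Data.frame with columns `locus`, `allele_units`,
#'   `freq`; per locus the alleles must be distinct and the frequencies
#'   non-negative and summing to 1 (tolerance 1e-9).
#' @param n_samples Number of diploid samples (>= 1).
#' @param seed Integer seed.
#' @param cohort Cohort name written into the calls table.
#' @return List of class `"synthetic_cohort"`: `$calls` (data.frame
#'   `sample`, `cohort`, `locus`, `a1`, `a2`) and `$truth` (per-locus
#'   expected heterozygosity `1 - sum(p_i^2)`).
#' @export
make_cohort <- function(spectra, n_samples, seed, cohort = "cohort") {
  stopifnot(is.data.frame(spectra),
            all(c("locus", "allele_units", "freq") %in% names(spectra)))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  if (any(spectra$freq < 0)) stop("negative allele frequency", call. = FALSE)
  loci <- unique(spectra$locus)
  for (l in loci) {
    g <- spectra[spectra$locus == l, ]
    if (anyDuplicated(g$allele_units)) {
      stop("duplicate alleles in spectrum for ", l, call. = FALSE)
    }
    if (abs(sum(g$freq) - 1) > 1e-9) {
      stop("allele frequencies for ", l, " sum to ", sum(g$freq),
           ", not 1", call. = FALSE)
    }
  }
  set.seed(seed)
  samples <- sprintf("S%04d", seq_len(n_samples))
  calls <- do.call(rbind, lapply(loci, function(l) {
    g <- spectra[spectra$locus == l, ]
    idx <- sample.int(nrow(g), 2L * n_samples, replace = TRUE,
                      prob = g$freq)   # index draw: safe for 1-allele spectra
    draw <- matrix(g$allele_units[idx], ncol = 2L)
    data.frame(sample = samples, cohort = cohort, locus = l,
               a1 = draw[, 1], a2 = draw[, 2], stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(loci, function(l) {
    g <- spectra[spectra$locus == l, ]
    data.frame(locus = l, exp_het = 1 - sum(g$freq^2),
               stringsAsFactors = FALSE)
  }))
  structure(list(calls = calls, truth = truth, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", length(unique(x$calls$sample)), " samples x ",
      length(unique(x$calls$locus)), " loci, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write simulated cohort calls as TSV
#'
#' Layout `sample cohort locus a1_units a2_units`, readable by
#' [read_calls()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$calls
  out <- data.frame(sample = df$sample, cohort = df$cohort, locus = df$locus,
                    a1_units = df$a1, a2_units = df$a2,
                    stringsAsFactors = FALSE)
  write_tsv_atomic(out, path)
}
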