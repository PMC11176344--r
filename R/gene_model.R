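# Transcript models for region annotation.
#
# Internal representation (class "gene_model"):
#   $transcripts: data.frame tx_id, gene, chrom, strand, tx_start, tx_end,
#                 cds_start, cds_end (NA when noncoding), coding
#   $exons:       data.frame tx_id, start, end
# All coordinates 0-based half-open. Two input dialects are accepted and
# normalized: GFF3 (1-based inclusive) and refGene-style TSV (UCSC
# convention: 0-based half-open starts). The reader logs which dialect it
# detected.

new_gene_model <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  transcripts <- transcripts[order(transcripts$chrom, transcripts$tx_start,
                                   transcripts$tx_id), , drop = FALSE]
  rownames(transcripts) <- NULL
  for (id in transcripts$tx_id) {
    ex <- exons[exons$tx_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", id, call. = FALSE)
    }
    tx <- transcripts[transcripts$tx_id == id, ]
    if (tx$coding) {
      if (is.na(tx$cds_start) || is.na(tx$cds_end) ||
          tx$cds_start < tx$tx_start || tx$cds_end > tx$tx_end) {
        stop("CDS outside transcript span in ", id, call. = FALSE)
      }
    }
  }
  structure(list(transcripts = transcripts,
                 exons = exons[order(exons$tx_id, exons$start), , drop = FALSE]),
            class = "gene_model")
}

#' Construct a gene model from transcript and exon tables
#'
#' Programmatic constructor for the container [read_gene_model()] builds
#' from files. Coordinates are 0-based half-open.
#'
#' @param transcripts Data.frame with columns `tx_id`, `gene`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end` (`NA` for noncoding), `coding` (logical).
#' @param exons Data.frame with columns `tx_id`, `start`, `end`; exons of
#'   a transcript must not overlap.
#' @return A `gene_model` object.
#' @export
gene_model <- function(transcripts, exons) {
  new_gene_model(transcripts, exons)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model: ", nrow(x$transcripts), " transcripts (",
      sum(x$transcripts$coding), " coding) on ",
      length(unique(x$transcripts$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a gene model (GFF3 or refGene-style TSV)
#'
#' Accepts either GFF3 (detected by extension `.gff`/`.gff3`/`.gff.gz` or a
#' `##gff-version` first line) or a refGene-style tab-separated transcript
#' table with columns `name chrom strand txStart txEnd cdsStart cdsEnd
#' exonCount exonStarts exonEnds gene`. GFF3 coordinates (1-based
#' inclusive) and refGene coordinates (0-based half-open) are both
#' normalized to the internal 0-based half-open convention; a message
#' states which dialect was detected. A transcript with an empty CDS
#' (refGene `cdsStart == cdsEnd`, or no CDS features in GFF3) is treated
#' as noncoding.
#'
#' @param path Input file.
#' @param quiet Suppress the dialect log message.
#' @return A `gene_model` object.
#' @export
read_gene_model <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  is_gff <- grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
  if (!is_gff) {
    first <- readLines(path, n = 1L)
    is_gff <- length(first) == 1L && startsWith(first, "##gff-version")
  }
  if (is_gff) {
    if (!quiet) message("[genes] reading GFF3 (1-based inclusive): ", path)
    read_gene_model_gff3(path)
  } else {
    if (!quiet) message("[genes] reading refGene-style TSV (0-based half-open starts): ", path)
    read_gene_model_refgene(path)
  }
}

TX_TYPES <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "lincRNA",
              "snoRNA", "snRNA", "miRNA", "rRNA", "tRNA",
              "pseudogenic_transcript", "antisense_RNA")

read_gene_model_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  txs <- gr[type %in% TX_TYPES]
  if (length(txs) == 0L) stop("no transcript features in ", path, call. = FALSE)
  tx_id <- as.character(txs$ID)
  gene <- if (!is.null(txs$gene_name)) as.character(txs$gene_name) else tx_id
  gene[is.na(gene)] <- tx_id[is.na(gene)]

  parent_of <- function(sub) {
    p <- sub$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v[1]) else NA_character_,
           character(1))
  }
  exons_gr <- gr[type == "exon"]
  cds_gr <- gr[type == "CDS"]
  exon_parent <- parent_of(exons_gr)
  cds_parent <- parent_of(cds_gr)

  tx_rows <- data.frame(
    tx_id = tx_id, gene = gene,
    chrom = as.character(GenomicRanges::seqnames(txs)),
    strand = as.character(GenomicRanges::strand(txs)),
    tx_start = GenomicRanges::start(txs) - 1L,
    tx_end = GenomicRanges::end(txs),
    cds_start = NA_integer_, cds_end = NA_integer_,
    coding = FALSE, stringsAsFactors = FALSE)
  tx_rows$strand[!tx_rows$strand %in% c("+", "-")] <- "+"

  ex_rows <- data.frame(tx_id = exon_parent,
                        start = GenomicRanges::start(exons_gr) - 1L,
                        end = GenomicRanges::end(exons_gr),
                        stringsAsFactors = FALSE)
  ex_rows <- ex_rows[!is.na(ex_rows$tx_id) & ex_rows$tx_id %in% tx_rows$tx_id, ]
  for (i in seq_len(nrow(tx_rows))) {
    id <- tx_rows$tx_id[i]
    cd <- which(cds_parent == id)
    if (length(cd)) {
      tx_rows$cds_start[i] <- min(GenomicRanges::start(cds_gr)[cd]) - 1L
      tx_rows$cds_end[i] <- max(GenomicRanges::end(cds_gr)[cd])
      tx_rows$coding[i] <- TRUE
    }
    if (!any(ex_rows$tx_id == id)) {
      # transcript with no exon children: treat its span as one exon
      ex_rows <- rbind(ex_rows, data.frame(tx_id = id,
                                           start = tx_rows$tx_start[i],
                                           end = tx_rows$tx_end[i],
                                           stringsAsFactors = FALSE))
    }
  }
  new_gene_model(tx_rows, ex_rows)
}

read_gene_model_refgene <- function(path) {
  df <- read_tsv(path)
  need <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonCount", "exonStarts", "exonEnds", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("refGene-style table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  coding <- df$cdsStart != df$cdsEnd
  tx_rows <- data.frame(
    tx_id = as.character(df$name), gene = as.character(df$gene),
    chrom = as.character(df$chrom), strand = as.character(df$strand),
    tx_start = as.integer(df$txStart), tx_end = as.integer(df$txEnd),
    cds_start = ifelse(coding, as.integer(df$cdsStart), NA_integer_),
    cds_end = ifelse(coding, as.integer(df$cdsEnd), NA_integer_),
    coding = coding, stringsAsFactors = FALSE)
  split_pos <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  ex_rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    st <- split_pos(df$exonStarts[i]); en <- split_pos(df$exonEnds[i])
    if (length(st) != df$exonCount[i] || length(en) != df$exonCount[i]) {
      stop("exon list length disagrees with exonCount for ", df$name[i],
           call. = FALSE)
    }
    data.frame(tx_id = as.character(df$name[i]), start = st, end = en,
               stringsAsFactors = FALSE)
  }))
  new_gene_model(tx_rows, ex_rows)
}
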