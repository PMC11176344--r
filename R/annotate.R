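# Gene-based functional region annotation.
#
# Every locus receives exactly one of 13 region labels. Candidate labels
# are collected per overlapping/nearby transcript, then resolved by a
# fixed precedence order (exonic outranks intronic outranks flanking).

#' The 13 functional region labels
#'
#' Returned in report-column order (the layout of the categorization
#' matrix). The annotation precedence order is different; see
#' [region_precedence()].
#'
#' @return Character vector of the 13 labels.
#' @export
region_labels <- function() {
  c("Coding", "Splicing", "Exonic;Splicing", "3'UTR", "5'UTR",
    "5'UTR;3'UTR", "Intergenic", "Intronic", "ncRNA-Exonic",
    "ncRNA-Intronic", "Upstream", "Downstream", "Upstream/Downstream")
}

#' Label precedence for multi-transcript conflict resolution
#'
#' Highest precedence first. A locus earning several labels from several
#' transcripts is reported with the highest-precedence one; exonic labels
#' outrank intronic ones, which outrank flanking ones, with Intergenic as
#' the floor.
#'
#' @return Character vector of the 13 labels, highest precedence first.
#' @export
region_precedence <- function() {
  c("Exonic;Splicing", "Coding", "Splicing", "5'UTR;3'UTR", "5'UTR",
    "3'UTR", "ncRNA-Exonic", "Intronic", "ncRNA-Intronic",
    "Upstream/Downstream", "Upstream", "Downstream", "Intergenic")
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

#' Classify one locus against one transcript
#'
#' Returns the single region label the locus earns from this transcript,
#' or `NA` if the transcript neither overlaps the locus nor lies within
#' the upstream/downstream window. Rules, in order: overlap with the CDS
#' gives Coding; overlap with intronic bases within `splice_window` of an
#' internal exon boundary gives Splicing (exonic + splicing together give
#' Exonic;Splicing); overlap with UTR exon bases gives 5'UTR / 3'UTR
#' (strand-aware; both give 5'UTR;3'UTR); inside the span with no exon
#' contact gives Intronic. For noncoding transcripts: exon overlap gives
#' ncRNA-Exonic, otherwise ncRNA-Intronic. Outside the span, a gap of
#' less than `upstream_window` bases (0 = adjacent) on the transcription-
#' start side gives Upstream, on the other side Downstream.
#'
#' @param l_start,l_end Locus interval, 0-based half-open.
#' @param l_chrom Locus chromosome.
#' @param model A `gene_model`.
#' @param tx_id Transcript to classify against.
#' @param upstream_window,splice_window Window sizes in bp (defaults 1000
#'   and 2, the conventional gene-annotation windows).
#' @return A label string or `NA_character_`.
#' @export
classify_against_transcript <- function(l_start, l_end, l_chrom, model, tx_id,
                                        upstream_window = 1000L,
                                        splice_window = 2L) {
  tx <- model$transcripts[model$transcripts$tx_id == tx_id, ]
  if (nrow(tx) != 1L) stop("unknown transcript: ", tx_id, call. = FALSE)
  ex <- model$exons[model$exons$tx_id == tx_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  classify_one(l_start, l_end, l_chrom, tx, ex, upstream_window, splice_window)
}

classify_one <- function(l_start, l_end, l_chrom, tx, ex,
                         upstream_window, splice_window) {
  if (l_chrom != tx$chrom) return(NA_character_)
  minus <- tx$strand == "-"

  if (!overlaps(l_start, l_end, tx$tx_start, tx$tx_end)) {
    # flanking: gap measured base-to-nearest-base, 0 meaning adjacent
    if (l_end <= tx$tx_start) {
      gap <- tx$tx_start - l_end
      side <- if (minus) "Downstream" else "Upstream"
    } else {
      gap <- l_start - tx$tx_end
      side <- if (minus) "Upstream" else "Downstream"
    }
    return(if (gap < upstream_window) side else NA_character_)
  }

  exon_hit <- any(l_start < ex$end & ex$start < l_end)

  # splicing: overlap with intronic bases within splice_window of an
  # internal exon boundary
  splice_hit <- FALSE
  if (splice_window > 0L && nrow(ex) > 1L) {
    donor <- ex$end[-nrow(ex)]     # intron starts
    accep <- ex$start[-1]          # intron ends
    splice_hit <- any(l_start < donor + splice_window & donor < l_end) ||
      any(l_start < accep & accep - splice_window < l_end)
  }

  if (!tx$coding) {
    if (exon_hit) return("ncRNA-Exonic")
    return("ncRNA-Intronic")
  }

  cds_hit <- FALSE; utr5_hit <- FALSE; utr3_hit <- FALSE
  if (exon_hit) {
    for (k in seq_len(nrow(ex))) {
      os <- max(l_start, ex$start[k]); oe <- min(l_end, ex$end[k])
      if (os >= oe) next
      if (overlaps(os, oe, tx$cds_start, tx$cds_end)) cds_hit <- TRUE
      if (os < tx$cds_start) {       # exonic bases 5' (in genome coords) of CDS
        if (minus) utr3_hit <- TRUE else utr5_hit <- TRUE
      }
      if (oe > tx$cds_end) {
        if (minus) utr5_hit <- TRUE else utr3_hit <- TRUE
      }
    }
  }

  exonic <- cds_hit || utr5_hit || utr3_hit
  if (exonic && splice_hit) return("Exonic;Splicing")
  if (cds_hit) return("Coding")
  if (utr5_hit && utr3_hit) return("5'UTR;3'UTR")
  if (utr5_hit) return("5'UTR")
  if (utr3_hit) return("3'UTR")
  if (splice_hit) return("Splicing")
  "Intronic"
}

#' Annotate repeat loci against a gene model
#'
#' Collects candidate labels for every locus across all transcripts within
#' reach and resolves each to exactly one label by [region_precedence()].
#' A locus that is Upstream of one transcript and Downstream of another is
#' labeled Upstream/Downstream. The gene and transcript of the winning
#' label are reported (ties broken by transcript id for determinism);
#' both are empty exactly when the label is Intergenic.
#'
#' @param loci Locus table from [scan_sequence()]/[scan_fasta()].
#' @param model A `gene_model`.
#' @param upstream_window,splice_window See [classify_against_transcript()].
#' @param unknown_chrom `"intergenic"` (default) labels loci on
#'   chromosomes absent from the model Intergenic with a warning;
#'   `"error"` rejects them.
#' @return `loci` with columns `label`, `gene`, `transcript` appended;
#'   one row per input row, same order.
#' @export
annotate_loci <- function(loci, model, upstream_window = 1000L,
                          splice_window = 2L,
                          unknown_chrom = c("intergenic", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  stopifnot(inherits(model, "gene_model"))
  n <- nrow(loci)
  label <- character(n); gene <- character(n); transcript <- character(n)
  prec <- region_precedence()
  txs <- model$transcripts

  missing_chr <- setdiff(unique(loci$chrom), unique(txs$chrom))
  if (length(missing_chr)) {
    if (unknown_chrom == "error") {
      stop("loci on chromosome(s) absent from the gene model: ",
           paste(missing_chr, collapse = ", "), call. = FALSE)
    }
    if (any(loci$chrom %in% missing_chr)) {
      warning("labelling loci Intergenic on chromosome(s) absent from the ",
              "gene model: ", paste(missing_chr, collapse = ", "),
              call. = FALSE)
    }
  }

  exons_by_tx <- split(model$exons, model$exons$tx_id)
  for (i in seq_len(n)) {
    ls <- loci$start0[i]; le <- loci$end0[i]; lc <- loci$chrom[i]
    cand_label <- character(0); cand_tx <- character(0)
    idx <- which(txs$chrom == lc &
                   ls < txs$tx_end + upstream_window &
                   txs$tx_start - upstream_window < le)
    for (j in idx) {
      ex <- exons_by_tx[[txs$tx_id[j]]]
      ex <- ex[order(ex$start), , drop = FALSE]
      lab <- classify_one(ls, le, lc, txs[j, ], ex,
                          upstream_window, splice_window)
      if (!is.na(lab)) {
        cand_label <- c(cand_label, lab)
        cand_tx <- c(cand_tx, txs$tx_id[j])
      }
    }
    if (!length(cand_label)) {
      label[i] <- "Intergenic"; gene[i] <- ""; transcript[i] <- ""
      next
    }
    if (any(cand_label == "Upstream") && any(cand_label == "Downstream")) {
      # merged flanking label; attribute to the upstream transcript
      up_tx <- sort(cand_tx[cand_label == "Upstream"])[1]
      cand_label <- c(cand_label, "Upstream/Downstream")
      cand_tx <- c(cand_tx, up_tx)
    }
    if (any(cand_label == "5'UTR") && any(cand_label == "3'UTR")) {
      # one locus in the 5'UTR of one transcript and the 3'UTR of another
      utr_tx <- sort(cand_tx[cand_label == "5'UTR"])[1]
      cand_label <- c(cand_label, "5'UTR;3'UTR")
      cand_tx <- c(cand_tx, utr_tx)
    }
    ranks <- match(cand_label, prec)
    best <- which(ranks == min(ranks))
    pick <- best[order(cand_tx[best])][1]
    label[i] <- cand_label[pick]
    transcript[i] <- cand_tx[pick]
    gene[i] <- txs$gene[match(cand_tx[pick], txs$tx_id)]
  }
  out <- loci
  out$label <- label
  out$gene <- gene
  out$transcript <- transcript
  out
}

#' Write an annotated locus table as TSV
#'
#' @param annotated Output of [annotate_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(annotated, path) {
  cols <- c("chrom", "start0", "end0", "unit", "n_units",
            "label", "gene", "transcript")
  write_tsv_atomic(annotated[, cols], path)
}
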