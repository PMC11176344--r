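# Maximal exact tandem-repeat detection.
#
# Coordinates are 0-based half-open internally; writers also emit 1-based
# inclusive columns. A run is "maximal" when it cannot be extended by one
# full motif copy on either side; partial trailing copies never count.

IUPAC_AMBIG <- "RYSWKMBDHVN"

empty_locus_table <- function() {
  data.frame(chrom = character(), start0 = integer(), end0 = integer(),
             unit = character(), n_units = integer(),
             seq_check = character(), stringsAsFactors = FALSE)
}

# Reject characters outside the IUPAC DNA alphabet, naming the first
# offending position (1-based).
validate_dna <- function(seq, chrom = "sequence") {
  bad <- regexpr(sprintf("[^ACGT%s]", IUPAC_AMBIG), seq, ignore.case = TRUE)
  if (bad != -1L) {
    stop("non-DNA character '", substr(seq, bad, bad), "' in ", chrom,
         " at position ", as.integer(bad), call. = FALSE)
  }
  invisible(TRUE)
}

sort_locus_table <- function(df) {
  df <- df[order(df$chrom, df$start0, df$unit), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect maximal exact tandem repeats in one sequence
#'
#' Finds, independently for every motif in `config`, all maximal runs of
#' contiguous exact copies with at least `min_units` full copies. A run is
#' maximal when it cannot be extended by one further full copy of the motif
#' on either side; partial copies are ignored (`"CAGCAGCA"` holds 2 units).
#' Runs of different motifs may overlap; each motif is scanned on its own.
#'
#' @param seq Character scalar of DNA (A/C/G/T, IUPAC ambiguity codes and
#'   lowercase allowed). Ambiguity codes (including N) split runs when
#'   `config$break_on_ambiguous` is `TRUE`.
#' @param chrom Name reported in the `chrom` column.
#' @param config A [scan_config()].
#' @return A data.frame with columns `chrom`, `start0`, `end0` (0-based
#'   half-open), `unit`, `n_units`, `seq_check` (the matched substring,
#'   case as found), sorted by (chrom, start0, unit).
#' @export
#' @examples
#' scan_sequence("TTCAGCAGCAGCAGAA", "toy", scan_config(motifs = "CAG"))
scan_sequence <- function(seq, chrom = "seq", config = scan_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!inherits(config, "scan_config")) {
    stop("config must be a scan_config object", call. = FALSE)
  }
  if (!nzchar(seq)) {
    return(empty_locus_table())
  }
  validate_dna(seq, chrom)
  subject <- if (config$case_sensitive) seq else toupper(seq)

  out <- lapply(config$motifs, function(unit) {
    ulen <- nchar(unit)
    pat <- if (config$break_on_ambiguous) {
      sprintf("(?:%s)+", unit)
    } else {
      # N acts as a wildcard for any motif base
      chars <- strsplit(unit, "")[[1]]
      sprintf("(?:%s)+", paste0("[", chars, "N]", collapse = ""))
    }
    m <- gregexpr(pat, subject, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    n_units <- lens %/% ulen            # greedy match is whole units already
    keep <- n_units >= config$min_units
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; n_units <- n_units[keep]
    start0 <- starts - 1L
    end0 <- start0 + n_units * ulen
    data.frame(chrom = chrom, start0 = start0, end0 = end0,
               unit = unit, n_units = n_units,
               seq_check = substring(seq, start0 + 1L, end0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(empty_locus_table())))
  if (config$dedup_frame_shifts && nrow(res) > 1L) {
    res <- dedup_frame_shifted(res)
  }
  sort_locus_table(res)
}

# Drop any locus wholly contained in a strictly longer locus of a
# rotationally equivalent motif (the GCC-inside-CCG case).
dedup_frame_shifted <- function(df) {
  canon <- vapply(df$unit, function(u) min(motif_rotations(u)), character(1))
  drop <- logical(nrow(df))
  for (cls in unique(canon)) {
    idx <- which(canon == cls)
    if (length(idx) < 2L) next
    for (i in idx) {
      for (j in idx) {
        if (i == j || df$unit[i] == df$unit[j]) next
        longer_j <- (df$end0[j] - df$start0[j]) > (df$end0[i] - df$start0[i])
        contained <- df$chrom[i] == df$chrom[j] &&
          df$start0[i] >= df$start0[j] && df$end0[i] <= df$end0[j]
        if (longer_j && contained) drop[i] <- TRUE
      }
    }
  }
  df[!drop, , drop = FALSE]
}

#' Scan a (multi-)FASTA file record by record
#'
#' Streams through a FASTA file (plain or gzip), applying [scan_sequence()]
#' to each record in file order and concatenating the results. One record
#' is held in memory at a time, so a whole-genome file can be scanned
#' without whole-genome residency.
#'
#' @param fasta_path Path to a FASTA file.
#' @param config A [scan_config()].
#' @param quiet Suppress the per-record progress log. Default `FALSE`.
#' @return Locus table as in [scan_sequence()], record order preserved.
#' @export
scan_fasta <- function(fasta_path, config = scan_config(), quiet = FALSE) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  idx <- Biostrings::fasta.index(fasta_path)
  names_ <- sub("\\s.*$", "", idx$desc)
  if (anyDuplicated(names_)) {
    stop("duplicate FASTA record names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  pieces <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    rec <- Biostrings::readDNAStringSet(idx[i, ])
    seq <- as.character(rec[[1]])
    pieces[[i]] <- scan_sequence(seq, chrom = names_[i], config = config)
    if (!quiet) {
      message("[scan] ", names_[i], ": ", nchar(seq), " bp, ",
              nrow(pieces[[i]]), " loci")
    }
  }
  res <- do.call(rbind, c(pieces, list(empty_locus_table())))
  rownames(res) <- NULL
  if (!quiet) message("[scan] total loci: ", nrow(res))
  res
}

#' Brute-force repeat-run oracle
#'
#' Declarative re-derivation of [scan_sequence()] for use in tests:
#' enumerates every (start, motif) pair, counts contiguous full copies by
#' direct substring comparison, and keeps a run iff it has at least
#' `min_units` copies and no further full copy immediately before or after
#' it. Quadratic; guarded to short sequences.
#'
#' @param seq DNA string, at most `guard` characters.
#' @param config A [scan_config()].
#' @param guard Maximum sequence length accepted (default 10000).
#' @return Locus table with the same columns and ordering as
#'   [scan_sequence()].
#' @export
brute_force_oracle <- function(seq, config = scan_config(), guard = 10000L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) > guard) {
    stop("sequence longer than the oracle guard bound (", guard, " bp)",
         call. = FALSE)
  }
  if (!nzchar(seq)) return(empty_locus_table())
  validate_dna(seq)
  raw <- seq
  subject <- if (config$case_sensitive) seq else toupper(seq)
  n <- nchar(subject)
  unit_at <- function(pos0, unit, ulen) {
    # does a full copy of unit occupy [pos0, pos0+ulen)?
    pos0 >= 0L && pos0 + ulen <= n &&
      substring(subject, pos0 + 1L, pos0 + ulen) == unit
  }
  rows <- list()
  for (unit in config$motifs) {
    ulen <- nchar(unit)
    for (s in 0:(n - 1L)) {
      if (!unit_at(s, unit, ulen)) next
      if (unit_at(s - ulen, unit, ulen)) next    # not leftmost full copy
      k <- 1L
      while (unit_at(s + k * ulen, unit, ulen)) k <- k + 1L
      if (k >= config$min_units) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "seq", start0 = s, end0 = s + k * ulen,
          unit = unit, n_units = k,
          seq_check = substring(raw, s + 1L, s + k * ulen),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(rows, list(empty_locus_table())))
  if (config$dedup_frame_shifts && nrow(res) > 1L) {
    res <- dedup_frame_shifted(res)
  }
  sort_locus_table(res)
}

#' Write a locus table as TSV (and optionally BED)
#'
#' The TSV carries both coordinate dialects: `start0`/`end0` (0-based
#' half-open, the internal convention) and `start1`/`end1` (1-based
#' inclusive, the convention of printed locus tables). The optional BED6
#' export uses 0-based half-open coordinates with `name = unit:n_units`,
#' `score = n_units` and strand `"+"`.
#'
#' @param loci Locus table from [scan_sequence()]/[scan_fasta()].
#' @param path Output TSV path.
#' @param bed_path Optional BED6 output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path, bed_path = NULL) {
  out <- data.frame(chrom = loci$chrom,
                    start0 = loci$start0, end0 = loci$end0,
                    start1 = loci$start0 + 1L, end1 = loci$end0,
                    unit = loci$unit, n_units = loci$n_units,
                    stringsAsFactors = FALSE)
  write_tsv_atomic(out, path)
  if (!is.null(bed_path)) {
    bed <- data.frame(loci$chrom, loci$start0, loci$end0,
                      paste0(loci$unit, ":", loci$n_units),
                      loci$n_units, "+", stringsAsFactors = FALSE)
    con <- file(bed_path, open = "wb")
    on.exit(close(con))
    if (nrow(bed)) {
      writeLines(do.call(paste, c(unname(bed), sep = "\t")), con)
    }
  }
  invisible(path)
}
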