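#' CNG repeat units screened by default
#'
#' The five trinucleotide units classically implicated in neurodegenerative
#' repeat-expansion disorders (polyglutamine and related loci): CAG, CCG,
#' CGG, CTG and GCC. These are the default motif set for [scan_sequence()]
#' and [scan_fasta()].
#'
#' @return Character vector of repeat units.
#' @export
#' @examples
#' cng_motifs()
cng_motifs <- function() c("CAG", "CCG", "CGG", "CTG", "GCC")

# TRUE if unit is a power of a strictly shorter unit ("AAA", "CACA", ...).
# Non-primitive motifs are rejected up front: for primitive motifs, maximal
# runs of one motif can never overlap each other, which is what makes the
# greedy scanner and the declarative oracle provably equivalent.
is_power_of_shorter <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0L &&
        strrep(substr(unit, 1L, p), n %/% p) == unit) {
      return(TRUE)
    }
  }
  FALSE
}

#' Validate a repeat motif
#'
#' A motif is a non-empty DNA string over A, C, G, T. It must be primitive
#' (not a repetition of a shorter unit, so e.g. `"AAA"` is rejected in
#' favour of `"A"`): primitivity guarantees that maximal runs of the same
#' motif never overlap, which keeps run detection unambiguous.
#'
#' @param unit Character scalar, the repeat unit (e.g. `"CAG"`).
#' @return The validated unit, upper-cased, invisibly usable downstream.
#' @export
repeat_motif <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit) || !nzchar(unit)) {
    stop("motif unit must be a single non-empty string", call. = FALSE)
  }
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) {
    stop("motif unit '", unit, "' contains characters outside A,C,G,T",
         call. = FALSE)
  }
  if (is_power_of_shorter(unit)) {
    stop("motif unit '", unit, "' is a repetition of a shorter unit; ",
         "use the shorter unit instead", call. = FALSE)
  }
  unit
}

#' Scan configuration
#'
#' Bundles the parameters of a repeat scan: the motif set, the minimum
#' number of contiguous exact copies a run must reach to be reported, and
#' the policies for case and ambiguous bases.
#'
#' @param motifs Character vector of repeat units (validated by
#'   [repeat_motif()]); duplicates are an error. Default [cng_motifs()].
#' @param min_units Minimum number of contiguous full copies (integer
#'   >= 2). Default 4, the classical screening threshold for trinucleotide
#'   repeat loci.
#' @param case_sensitive If `FALSE` (default) soft-masked (lowercase)
#'   sequence is scanned like uppercase; if `TRUE`, lowercase bases do not
#'   match the (uppercase) motifs.
#' @param break_on_ambiguous If `TRUE` (default) an N or any IUPAC
#'   ambiguity code splits a run; the two flanks are evaluated
#'   independently. If `FALSE`, N is treated as a wildcard matching any
#'   motif base.
#' @param dedup_frame_shifts If `TRUE`, suppress any run wholly contained
#'   in a longer run of a rotationally equivalent motif (e.g. the GCC run
#'   inside every CCG run). Default `FALSE`: each motif is tallied
#'   independently, one row per motif.
#' @return A list of class `"scan_config"`.
#' @export
#' @examples
#' scan_config(motifs = c("CAG", "CTG"), min_units = 5)
scan_config <- function(motifs = cng_motifs(), min_units = 4L,
                        case_sensitive = FALSE, break_on_ambiguous = TRUE,
                        dedup_frame_shifts = FALSE) {
  if (length(motifs) == 0L) {
    stop("motif set must be non-empty", call. = FALSE)
  }
  motifs <- vapply(motifs, repeat_motif, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(motifs)) {
    stop("duplicate motif units: ",
         paste(unique(motifs[duplicated(motifs)]), collapse = ", "),
         call. = FALSE)
  }
  min_units <- as.integer(min_units)
  if (is.na(min_units) || min_units < 2L) {
    stop("min_units must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(motifs = motifs, min_units = min_units,
         case_sensitive = isTRUE(case_sensitive),
         break_on_ambiguous = isTRUE(break_on_ambiguous),
         dedup_frame_shifts = isTRUE(dedup_frame_shifts)),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config: motifs {", paste(x$motifs, collapse = ", "),
      "}, min_units ", x$min_units,
      if (x$case_sensitive) ", case-sensitive" else ", case-insensitive",
      if (x$break_on_ambiguous) ", N breaks runs" else ", N is wildcard",
      if (x$dedup_frame_shifts) ", frame-shift dedup on" else "",
      "\n", sep = "")
  invisible(x)
}

# All rotations of a unit (including itself).
motif_rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n) - 1L, function(d) {
    paste0(substr(unit, d + 1L, n), substr(unit, 1L, d))
  }, character(1))
}
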