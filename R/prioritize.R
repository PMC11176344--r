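# Length-group categorization and candidate selection.

#' Assign repeat-length groups
#'
#' Group1 = 4-6 units, Group2 = 7-9 units, Group3 = 10 or more units.
#' Values below the scan minimum of 4 are rejected.
#'
#' @param n_units Integer vector of unit counts (each >= 4).
#' @return Character vector `"Group1"`/`"Group2"`/`"Group3"`.
#' @export
#' @examples
#' assign_group(c(4, 6, 7, 9, 10, 25))
assign_group <- function(n_units) {
  n_units <- as.integer(n_units)
  if (any(is.na(n_units)) || any(n_units < 4L)) {
    stop("n_units must all be >= 4 (the scan minimum)", call. = FALSE)
  }
  ifelse(n_units <= 6L, "Group1", ifelse(n_units <= 9L, "Group2", "Group3"))
}

#' Build the group x motif x region count matrix
#'
#' Tallies annotated loci into the 13 region labels per (length group,
#' motif) row, in the canonical report layout: one row per group x motif
#' combination (groups in order, motifs in the order given), 13 region
#' columns in [region_labels()] order, plus a recomputed `total` column.
#' Every annotated locus lands in exactly one cell, so the grand total
#' equals the input row count.
#'
#' @param annotated Output of [annotate_loci()].
#' @param motifs Motif rows to emit (default [cng_motifs()]); motifs
#'   present in the data but not listed are appended.
#' @return A data.frame of class `"count_matrix"` with columns `group`,
#'   `unit`, the 13 labels, `total`.
#' @export
summarize_matrix <- function(annotated, motifs = cng_motifs()) {
  labs <- region_labels()
  motifs <- union(motifs, unique(annotated$unit))
  groups <- c("Group1", "Group2", "Group3")
  grid <- expand.grid(unit = motifs, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("group", "unit")]
  mat <- matrix(0L, nrow = nrow(grid), ncol = length(labs),
                dimnames = list(NULL, labs))
  if (nrow(annotated)) {
    if (!all(annotated$label %in% labs)) {
      stop("unknown region label(s): ",
           paste(setdiff(unique(annotated$label), labs), collapse = ", "),
           call. = FALSE)
    }
    g <- assign_group(annotated$n_units)
    ri <- match(paste(g, annotated$unit), paste(grid$group, grid$unit))
    ci <- match(annotated$label, labs)
    for (k in seq_along(ri)) mat[ri[k], ci[k]] <- mat[ri[k], ci[k]] + 1L
  }
  out <- cbind(grid, as.data.frame(mat, check.names = FALSE))
  out$total <- as.integer(rowSums(mat))
  class(out) <- c("count_matrix", "data.frame")
  out
}

#' Write the categorization matrix as TSV
#'
#' Emits the exact report column order (group, unit, 13 region columns,
#' total); the total column is always recomputed from the cells, never
#' copied in.
#'
#' @param matrix A `count_matrix` from [summarize_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  labs <- region_labels()
  stopifnot(all(c("group", "unit", labs) %in% names(matrix)))
  out <- matrix[, c("group", "unit", labs)]
  out$total <- as.integer(rowSums(out[, labs]))
  write_tsv_atomic(out, path)
}

#' Select expansion-screening candidates
#'
#' The screening rule: keep loci whose reference unit count reaches
#' `min_units` and whose region label is coding or untranslated. The
#' default region set includes the combined exonic labels
#' (`Exonic;Splicing`, `5'UTR;3'UTR`); pass `combined = FALSE` to
#' restrict to the three pure labels. `strict_gt` switches the length
#' rule from `>= min_units` to `> min_units`.
#'
#' @param annotated Output of [annotate_loci()].
#' @param min_units Length threshold (default 10).
#' @param regions Region label set; overrides `combined` when given.
#' @param combined Include the combined exonic labels (default `TRUE`).
#' @param strict_gt Use a strict `>` length comparison (default `FALSE`).
#' @return The selected rows of `annotated`, input order preserved.
#' @export
select_candidates <- function(annotated, min_units = 10L, regions = NULL,
                              combined = TRUE, strict_gt = FALSE) {
  if (is.null(regions)) {
    regions <- c("Coding", "5'UTR", "3'UTR")
    if (combined) regions <- c(regions, "Exonic;Splicing", "5'UTR;3'UTR")
  }
  if (!length(regions)) {
    stop("candidate region set must be non-empty", call. = FALSE)
  }
  long_enough <- if (strict_gt) annotated$n_units > min_units
                 else annotated$n_units >= min_units
  annotated[long_enough & annotated$label %in% regions, , drop = FALSE]
}

#' Write the candidate table as TSV
#'
#' Candidate-report layout: gene, transcript, chrom, 1-based inclusive
#' coordinates, unit, label, n_units.
#'
#' @param candidates Output of [select_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- data.frame(gene = candidates$gene,
                    transcript = candidates$transcript,
                    chrom = candidates$chrom,
                    start1 = candidates$start0 + 1L,
                    end1 = candidates$end0,
                    unit = candidates$unit,
                    label = candidates$label,
                    n_units = candidates$n_units,
                    stringsAsFactors = FALSE)
  write_tsv_atomic(out, path)
}
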