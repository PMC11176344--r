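# Bundled results of the published hg19 CNG screen, shipped as plain-text
# tables for desk-scale consistency checks (the full genome scan needs
# the hg19 FASTA and a refGene snapshot, neither of which is bundled).

ref_path <- function(name) {
  system.file("extdata", name, package = "cngscreen", mustWork = TRUE)
}

#' Published genome-wide totals per length group and motif
#'
#' The fifteen (length group x repeat unit) locus totals of the hg19
#' screen. Summing the `total` column reproduces the genome-wide count
#' of 15,069 CNG repeat loci.
#'
#' @return Data.frame `group`, `unit`, `total` (15 rows).
#' @export
reference_group_totals <- function() {
  read_tsv(ref_path("hg19_cng_group_totals.tsv"))
}

#' Published candidate loci (52 CDS/UTR loci with >= 10 reference units)
#'
#' The screening candidates of the hg19 run: gene, transcript, printed
#' 1-based chromosome coordinates, repeat unit, region label, reference
#' unit count, the control-cohort allele range (repeat units, 100
#' genotyped controls), and the published variability call (`variable`
#' = 1 for the 19 polymorphic loci).
#'
#' @return Data.frame with 52 rows.
#' @export
reference_candidates <- function() {
  read_tsv(ref_path("hg19_candidate_loci.tsv"))
}

#' Published per-locus statistics for the 19 polymorphic loci
#'
#' Control- and case-cohort allele-distribution statistics (chromosome
#' and allele counts, range, mean, SD, median, heterozygosity index) for
#' the 19 loci called polymorphic in the control screen.
#'
#' @return Data.frame with 38 rows (19 genes x control/case).
#' @export
reference_polymorphic <- function() {
  read_tsv(ref_path("hg19_polymorphic_loci.tsv"))
}

#' The documented single-locus stability override
#'
#' One published polymorphic call (RAI1, control range 11-17) sits below
#' the span-7 rule that reproduces every other call; the published set is
#' reproduced verbatim by forcing this locus polymorphic. See
#' [classify_stability()].
#'
#' @return Character vector of gene symbols.
#' @export
reference_override <- function() "RAI1"
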