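# End-to-end pipeline driver: scan -> annotate -> categorize -> select,
# plus optional genotype analytics, with a machine-readable run manifest.

#' Run the screening pipeline
#'
#' Executes the stages in order — repeat scan over a FASTA, gene-model
#' annotation, count-matrix categorization, candidate selection, and
#' (when genotype calls are supplied) per-locus cohort summaries with
#' stability classification and an optional two-cohort comparison — and
#' writes each stage's table plus a JSON manifest to `out_dir`. All
#' writes are atomic (temp file + rename) and, for fixed inputs and
#' configuration, byte-identical across re-runs.
#'
#' @param config A list (or path to a YAML file holding one) with
#'   entries: `fasta` (required), `genes` (gene model path; optional —
#'   without it only the scan runs), `out_dir` (required), and optional
#'   `motifs`, `min_units` (default 4), `case_sensitive`,
#'   `break_on_ambiguous`, `dedup_frames`, `upstream_window`,
#'   `splice_window`, `select_min_units` (default 10), `select_combined`,
#'   `select_strict_gt`, `calls` (genotype TSV), `locus_config`,
#'   `stability_threshold` (default 7), `override_polymorphic`,
#'   `compare_locus` (run a rank-sum comparison at this locus between the
#'   first two cohorts in `calls`).
#' @param quiet Suppress stage logging.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  need <- function(key, stage) {
    if (is.null(config[[key]])) {
      stop("stage '", stage, "': missing required input '", key, "'",
           call. = FALSE)
    }
    config[[key]]
  }
  getd <- function(key, default) if (is.null(config[[key]])) default else config[[key]]

  out_dir <- need("out_dir", "setup")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  inputs <- character(0)
  add_file <- function(name, path, rows) {
    files[[name]] <<- list(path = basename(path), rows = rows)
  }

  scfg <- scan_config(motifs = getd("motifs", cng_motifs()),
                      min_units = getd("min_units", 4L),
                      case_sensitive = getd("case_sensitive", FALSE),
                      break_on_ambiguous = getd("break_on_ambiguous", TRUE),
                      dedup_frame_shifts = getd("dedup_frames", FALSE))

  fasta <- need("fasta", "scan")
  inputs["fasta"] <- fasta
  say("scan", "scanning ", fasta)
  loci <- scan_fasta(fasta, scfg, quiet = quiet)
  p <- file.path(out_dir, "loci.tsv")
  write_locus_table(loci, p, bed_path = if (isTRUE(config$bed))
    file.path(out_dir, "loci.bed") else NULL)
  add_file("loci", p, nrow(loci))
  say("scan", nrow(loci), " loci")

  annotated <- NULL
  if (!is.null(config$genes)) {
    inputs["genes"] <- config$genes
    model <- read_gene_model(config$genes, quiet = quiet)
    annotated <- annotate_loci(loci, model,
                               upstream_window = getd("upstream_window", 1000L),
                               splice_window = getd("splice_window", 2L))
    p <- file.path(out_dir, "annotated.tsv")
    write_annotated_table(annotated, p)
    add_file("annotated", p, nrow(annotated))
    say("annotate", nrow(annotated), " loci labelled")

    mat <- summarize_matrix(annotated, motifs = scfg$motifs)
    p <- file.path(out_dir, "matrix.tsv")
    write_count_matrix(mat, p)
    add_file("matrix", p, nrow(mat))
    say("categorize", "grand total ", sum(mat$total))

    cand <- select_candidates(annotated,
                              min_units = getd("select_min_units", 10L),
                              combined = getd("select_combined", TRUE),
                              strict_gt = getd("select_strict_gt", FALSE))
    p <- file.path(out_dir, "candidates.tsv")
    write_candidate_table(cand, p)
    add_file("candidates", p, nrow(cand))
    say("select", nrow(cand), " candidate loci")
  }

  if (!is.null(config$calls)) {
    inputs["calls"] <- config$calls
    calls <- read_calls(config$calls, locus_config = config$locus_config)
    if (!is.null(config$locus_config)) inputs["locus_config"] <- config$locus_config
    thr <- getd("stability_threshold", 7L)
    ov <- getd("override_polymorphic", character())
    cohorts <- unique(calls$cohort)
    summ <- do.call(rbind, lapply(cohorts, function(co) {
      s <- summarize_cohort(calls[calls$cohort == co, ], threshold = thr,
                            override_polymorphic = ov)
      cbind(cohort = co, s, stringsAsFactors = FALSE)
    }))
    p <- file.path(out_dir, "summary.tsv")
    write_tsv_atomic(summ, p)
    add_file("summary", p, nrow(summ))
    say("genotype-stats", nrow(summ), " locus summaries over ",
        length(cohorts), " cohort(s)")

    stab <- summ[, c("cohort", "locus", "min", "max", "stability")]
    p <- file.path(out_dir, "stability.tsv")
    write_tsv_atomic(stab, p)
    add_file("stability", p, nrow(stab))

    if (!is.null(config$compare_locus)) {
      if (length(cohorts) < 2L) {
        stop("stage 'compare': need two cohorts in the calls table",
             call. = FALSE)
      }
      ht <- compare_cohorts(calls[calls$cohort == cohorts[1], ],
                            calls[calls$cohort == cohorts[2], ],
                            locus = config$compare_locus, mode = "rank_sum")
      cmp <- data.frame(locus = config$compare_locus,
                        statistic = unname(ht$statistic),
                        p_value = ht$p.value, method = ht$method,
                        stringsAsFactors = FALSE)
      p <- file.path(out_dir, "compare.tsv")
      write_tsv_atomic(cmp, p)
      add_file("compare", p, nrow(cmp))
      say("compare", "p = ", format(ht$p.value, digits = 4))
    }
  }

  manifest <- list(
    tool = "cngscreen",
    version = as.character(utils::packageVersion("cngscreen")),
    config = config[order(names(config))],
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = files)
  mpath <- file.path(out_dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, mpath)
  say("done", "manifest written to ", mpath)
  invisible(manifest)
}
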