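# Population repeat-variability analytics from diploid allele calls.
#
# Calls are one row per (sample, locus): two allele lengths in repeat
# units. All statistics are computed over the allele *multiset* (two
# alleles per sample), so "number of chromosomes" is twice the number of
# genotyped samples at that locus.

#' Convert a sized PCR fragment to repeat units
#'
#' Capillary fragment analysis reports product length in bp; subtracting
#' the locus-specific flanking length and dividing by the unit length
#' gives the repeat count. The result is rounded to the nearest integer;
#' a residual of more than 1 bp from an exact multiple triggers a warning
#' (off-grid sizing usually means a wrong flank length or a sizing
#' artifact).
#'
#' @param fragment_bp Numeric fragment size(s) in bp.
#' @param flank_bp Integer flanking (non-repeat) length in bp.
#' @param unit_len Repeat unit length in bp (default 3).
#' @return Integer vector of repeat unit counts.
#' @export
#' @examples
#' fragment_to_units(100, 70)      # 10 units
#' fragment_to_units(70 + 3 * 7, 70)  # 7 units
fragment_to_units <- function(fragment_bp, flank_bp, unit_len = 3L) {
  if (unit_len < 1L) stop("unit_len must be >= 1", call. = FALSE)
  if (any(fragment_bp <= flank_bp)) {
    stop("fragment size must exceed the flanking length", call. = FALSE)
  }
  units <- as.integer(round((fragment_bp - flank_bp) / unit_len))
  resid <- abs(fragment_bp - flank_bp - units * unit_len)
  if (any(resid > 1)) {
    warning(sum(resid > 1), " fragment(s) more than 1 bp off an exact ",
            "repeat-unit multiple; check flank lengths", call. = FALSE)
  }
  units
}

# Normalize a calls data.frame: require sample/locus/a1/a2, order alleles
# a1 <= a2, reject duplicates and non-positive alleles.
normalize_calls <- function(calls) {
  need <- c("sample", "locus", "a1", "a2")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("calls table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(calls$a1 < 1 | calls$a2 < 1)) {
    stop("allele repeat counts must be >= 1", call. = FALSE)
  }
  cohort <- if ("cohort" %in% names(calls)) calls$cohort else ""
  key <- paste(cohort, calls$sample, calls$locus)
  if (anyDuplicated(key)) {
    stop("more than one call for (cohort, sample, locus): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  }
  lo <- pmin(calls$a1, calls$a2); hi <- pmax(calls$a1, calls$a2)
  calls$a1 <- lo; calls$a2 <- hi
  calls
}

# Smallest most-frequent value of an allele multiset.
allele_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])   # ties break toward the smaller
}

#' Summarize the allele distribution at one locus
#'
#' Statistics over the multiset of all alleles (two per genotyped
#' sample): range, mode (ties toward the smaller length), mean, sample
#' standard deviation (n-1 denominator), median, distinct allele count,
#' chromosome count, and the heterozygosity index HI = fraction of
#' samples whose two alleles differ (observed heterozygosity). Expected
#' heterozygosity (1 - sum of squared allele frequencies) is reported
#' alongside, clearly separated.
#'
#' @param calls Calls data.frame (`sample`, `locus`, `a1`, `a2`) for a
#'   single locus; at least one row.
#' @return One-row data.frame: `locus`, `n_chromosomes`, `n_alleles`,
#'   `min`, `max`, `mode`, `mean`, `sd`, `median`, `hi`, `exp_het`.
#' @export
#' @examples
#' calls <- data.frame(sample = paste0("S", 1:4), locus = "L1",
#'                     a1 = c(10, 12, 10, 10), a2 = c(12, 12, 10, 12))
#' locus_summary(calls)
locus_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no calls at locus", call. = FALSE)
  calls <- normalize_calls(calls)
  if (length(unique(calls$locus)) != 1L) {
    stop("locus_summary expects calls at a single locus; got: ",
         paste(unique(calls$locus), collapse = ", "), call. = FALSE)
  }
  alleles <- c(calls$a1, calls$a2)
  p <- as.numeric(table(alleles)) / length(alleles)
  data.frame(
    locus = calls$locus[1],
    n_chromosomes = length(alleles),
    n_alleles = length(unique(alleles)),
    min = min(alleles), max = max(alleles),
    mode = allele_mode(alleles),
    mean = mean(alleles),
    sd = if (length(alleles) > 1L) stats::sd(alleles) else 0,
    median = stats::median(alleles),
    hi = mean(calls$a1 != calls$a2),
    exp_het = 1 - sum(p^2),
    stringsAsFactors = FALSE)
}

#' Classify repeat stability from the observed variability span
#'
#' The variability span is `max - min` in repeat units over the cohort.
#' Loci with span of at least `threshold` units are called polymorphic
#' (expansion-prone screening hits), the rest stable. The rule is open-
#' ended upward. `override_polymorphic` forces named loci into the
#' polymorphic class regardless of span (for reproducing a published
#' locus set that deviates from the span rule at a single locus).
#'
#' @param min,max Numeric vectors of the smallest/largest allele (units).
#' @param threshold Span threshold in units (default 7).
#' @param locus Optional locus/gene names, parallel to `min`/`max`.
#' @param override_polymorphic Character vector of locus names forced to
#'   `"polymorphic"`.
#' @return Character vector `"stable"`/`"polymorphic"`.
#' @export
#' @examples
#' classify_stability(c(18, 6), c(23, 29))  # spans 5 and 23
classify_stability <- function(min, max, threshold = 7L, locus = NULL,
                               override_polymorphic = character()) {
  if (length(min) != length(max)) stop("min/max length mismatch", call. = FALSE)
  if (any(max < min)) stop("max < min", call. = FALSE)
  cls <- ifelse(max - min >= threshold, "polymorphic", "stable")
  if (length(override_polymorphic)) {
    if (is.null(locus)) {
      stop("override_polymorphic needs locus names", call. = FALSE)
    }
    cls[locus %in% override_polymorphic] <- "polymorphic"
  }
  cls
}

#' Per-locus summaries for a whole cohort
#'
#' Applies [locus_summary()] per locus and appends the stability class.
#'
#' @param calls Calls data.frame covering one cohort.
#' @param threshold,override_polymorphic Passed to [classify_stability()].
#' @return Data.frame, one row per locus, sorted by locus.
#' @export
summarize_cohort <- function(calls, threshold = 7L,
                             override_polymorphic = character()) {
  calls <- normalize_calls(calls)
  pieces <- lapply(split(calls, calls$locus), locus_summary)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$locus), , drop = FALSE]
  out$stability <- classify_stability(out$min, out$max, threshold,
                                      locus = out$locus,
                                      override_polymorphic = override_polymorphic)
  rownames(out) <- NULL
  out
}

#' Read a genotype calls table
#'
#' Two TSV layouts are accepted: repeat units
#' (`sample cohort locus a1_units a2_units`) or raw fragment sizes
#' (`sample cohort locus frag1_bp frag2_bp`) together with a per-locus
#' configuration table (`locus flank_bp unit_len`) used to convert sizes
#' with [fragment_to_units()].
#'
#' @param path Calls TSV.
#' @param locus_config Optional path to the per-locus flank table
#'   (required for the fragment-size layout).
#' @return Data.frame `sample`, `cohort`, `locus`, `a1`, `a2`.
#' @export
read_calls <- function(path, locus_config = NULL) {
  df <- read_tsv(path)
  if (all(c("a1_units", "a2_units") %in% names(df))) {
    out <- data.frame(sample = df$sample, cohort = df$cohort,
                      locus = df$locus,
                      a1 = as.integer(df$a1_units),
                      a2 = as.integer(df$a2_units),
                      stringsAsFactors = FALSE)
  } else if (all(c("frag1_bp", "frag2_bp") %in% names(df))) {
    if (is.null(locus_config)) {
      stop("fragment-size calls need a locus_config table ",
           "(locus, flank_bp, unit_len)", call. = FALSE)
    }
    cfg <- read_tsv(locus_config)
    need <- c("locus", "flank_bp", "unit_len")
    if (!all(need %in% names(cfg))) {
      stop("locus_config must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    m <- match(df$locus, cfg$locus)
    if (any(is.na(m))) {
      stop("locus_config missing locus/loci: ",
           paste(unique(df$locus[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    out <- data.frame(sample = df$sample, cohort = df$cohort,
                      locus = df$locus,
                      a1 = fragment_to_units(df$frag1_bp, cfg$flank_bp[m],
                                             cfg$unit_len[m]),
                      a2 = fragment_to_units(df$frag2_bp, cfg$flank_bp[m],
                                             cfg$unit_len[m]),
                      stringsAsFactors = FALSE)
  } else {
    stop("calls table must have columns a1_units/a2_units or ",
         "frag1_bp/frag2_bp", call. = FALSE)
  }
  normalize_calls(out)
}
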