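# External per-population STR allele catalogs (aggregated allele counts,
# e.g. public short-tandem-repeat databases), for cross-population
# comparison reports.

#' Load a per-population allele-count catalog
#'
#' Expects a TSV with columns `population`, `locus`, `allele_units`,
#' `count` (aggregated chromosome counts per allele length). Malformed
#' rows are rejected with their line number. An empty file yields an
#' empty catalog with a warning.
#'
#' @param path Catalog TSV.
#' @return Data.frame with the four columns, types validated.
#' @export
load_external_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(population = character(), locus = character(),
                      allele_units = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    warning("empty catalog file: ", path, call. = FALSE)
    return(empty)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("population", "locus", "allele_units", "count")
  if (!identical(header, need)) {
    stop("catalog header must be exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(lines) == 1L) {
    warning("catalog has no data rows: ", path, call. = FALSE)
    return(empty)
  }
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4L) {
      stop("malformed catalog row at line ", i, ": expected 4 fields, got ",
           length(fields), call. = FALSE)
    }
    units <- suppressWarnings(as.integer(fields[3]))
    cnt <- suppressWarnings(as.integer(fields[4]))
    if (is.na(units) || is.na(cnt) || units < 1L || cnt < 0L) {
      stop("malformed catalog row at line ", i,
           ": allele_units must be a positive integer and count a ",
           "non-negative integer", call. = FALSE)
    }
    data.frame(population = fields[1], locus = fields[2],
               allele_units = units, count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-population mode and range report
#'
#' Summarizes a catalog into the conventional cross-population layout:
#' one row per (locus, population) with the modal allele (count-weighted,
#' ties toward the smaller allele), the observed range, and the usual
#' `"mode (min-max)"` display string.
#'
#' @param catalog Output of [load_external_catalog()] (or any table with
#'   the same columns; zero-count alleles are ignored).
#' @return Data.frame `locus`, `population`, `mode`, `min`, `max`,
#'   `display`.
#' @export
catalog_report <- function(catalog) {
  catalog <- catalog[catalog$count > 0L, , drop = FALSE]
  if (nrow(catalog) == 0L) {
    return(data.frame(locus = character(), population = character(),
                      mode = integer(), min = integer(), max = integer(),
                      display = character(), stringsAsFactors = FALSE))
  }
  key <- interaction(catalog$locus, catalog$population, drop = TRUE)
  pieces <- lapply(split(catalog, key), function(g) {
    g <- g[order(g$allele_units), ]
    m <- g$allele_units[which.max(g$count)]
    data.frame(locus = g$locus[1], population = g$population[1],
               mode = m, min = min(g$allele_units), max = max(g$allele_units),
               display = sprintf("%d (%d-%d)", m, min(g$allele_units),
                                 max(g$allele_units)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$locus, out$population), ]
  rownames(out) <- NULL
  out
}

#' Expand a catalog into pseudo-calls for cohort comparison
#'
#' Turns aggregated allele counts for one population into an allele
#' vector (each allele repeated `count` times), usable as one side of a
#' rank-sum comparison against a genotyped cohort's allele multiset.
#'
#' @param catalog Catalog data.frame.
#' @param population,locus Selection.
#' @return Integer vector of allele lengths (one entry per chromosome).
#' @export
catalog_alleles <- function(catalog, population, locus) {
  g <- catalog[catalog$population == population & catalog$locus == locus, ]
  if (nrow(g) == 0L) {
    stop("no catalog entries for ", locus, " in ", population, call. = FALSE)
  }
  rep(g$allele_units, g$count)
}
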