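# Small TSV helpers shared by the report writers. All writers go through
# write_tsv_atomic so a crashed run never leaves a half-written table, and
# so outputs are byte-stable across re-runs (fixed EOL, no quoting, fixed
# number formatting via format()).

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")   # binary: identical bytes on every platform
  ok <- FALSE
  tryCatch({
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
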