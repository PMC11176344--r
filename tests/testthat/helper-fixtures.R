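# Fixture builders shared across test files. Everything is generated in
# code; nothing binary is stored.

# A single coding transcript on "+": exons [100,200) [300,400) [500,600),
# CDS [150,550). 5'UTR = [100,150), 3'UTR = [550,600).
toy_coding_model <- function(strand = "+") {
  gene_model(
    transcripts = data.frame(
      tx_id = "TX1", gene = "G1", chrom = "chr1", strand = strand,
      tx_start = 100L, tx_end = 600L, cds_start = 150L, cds_end = 550L,
      coding = TRUE, stringsAsFactors = FALSE),
    exons = data.frame(tx_id = "TX1",
                       start = c(100L, 300L, 500L),
                       end = c(200L, 400L, 600L),
                       stringsAsFactors = FALSE))
}

toy_noncoding_model <- function() {
  gene_model(
    transcripts = data.frame(
      tx_id = "NC1", gene = "G2", chrom = "chr1", strand = "+",
      tx_start = 1000L, tx_end = 1500L,
      cds_start = NA_integer_, cds_end = NA_integer_,
      coding = FALSE, stringsAsFactors = FALSE),
    exons = data.frame(tx_id = "NC1",
                       start = c(1000L, 1300L), end = c(1100L, 1500L),
                       stringsAsFactors = FALSE))
}

# Locus row in scan-output shape.
locus_row <- function(start0, end0, chrom = "chr1", unit = "CAG") {
  data.frame(chrom = chrom, start0 = start0, end0 = end0, unit = unit,
             n_units = max(1L, (end0 - start0) %/% nchar(unit)),
             stringsAsFactors = FALSE)
}

# Serialize a gene_model to a refGene-style TSV (UCSC dialect: 0-based
# half-open starts), for dialect-equivalence tests.
write_refgene <- function(model, path) {
  txs <- model$transcripts
  rows <- lapply(seq_len(nrow(txs)), function(j) {
    tx <- txs[j, ]
    ex <- model$exons[model$exons$tx_id == tx$tx_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    data.frame(name = tx$tx_id, chrom = tx$chrom, strand = tx$strand,
               txStart = tx$tx_start, txEnd = tx$tx_end,
               cdsStart = ifelse(tx$coding, tx$cds_start, tx$tx_start),
               cdsEnd = ifelse(tx$coding, tx$cds_end, tx$tx_start),
               exonCount = nrow(ex),
               exonStarts = paste0(paste(ex$start, collapse = ","), ","),
               exonEnds = paste0(paste(ex$end, collapse = ","), ","),
               gene = tx$gene, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random DNA string.
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive rank-sum p-value by enumerating all n1-subsets of pooled ranks.
enum_rank_sum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  sums <- combn(N, n1, function(idx) sum(r[idx]))
  p_le <- mean(sums <= W + 1e-9)
  p_ge <- mean(sums >= W - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le, greater = p_ge)
}

# Exhaustive signed-rank p-value over all 2^n sign patterns.
enum_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  sums <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(sums <= V + 1e-9)
  p_ge <- mean(sums >= V - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le, greater = p_ge)
}
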