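# Exact Wilcoxon tests with midrank tie handling.
#
# Base wilcox.test() declines to compute exact p-values in the presence
# of ties; these implementations compute the exact conditional null
# distribution given the observed (mid)ranks, which is the appropriate
# permutation null for tied repeat-length data. Doubled midranks keep
# all sums integral, so the distributions are built by integer
# subset-sum dynamic programming. Counts stay below 2^53 for the sample
# sizes where the exact path is used, so double arithmetic is exact.

# Distribution of the sum of `k` values drawn without replacement from
# `vals` (integers): returns named vector of counts over achievable sums.
subset_sum_counts <- function(vals, k) {
  smax <- sum(sort(vals, decreasing = TRUE)[seq_len(k)])
  # f[j+1, s+1] = number of j-subsets with sum s
  f <- matrix(0, nrow = k + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in vals) {
    jmax <- k
    for (j in jmax:1L) {
      src <- f[j, seq_len(smax + 1L - v)]
      if (any(src != 0)) {
        idx <- (v + 1L):(smax + 1L)
        f[j + 1L, idx] <- f[j + 1L, idx] + src
      }
    }
  }
  f[k + 1L, ]
}

two_sided_p <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Exact/approximate Wilcoxon rank-sum test with midranks
#'
#' Compares two samples by the rank-sum statistic W = sum of the
#' (mid)ranks of `x` in the pooled sample. When the smaller sample has at
#' most `exact_max_n` observations the exact conditional null
#' distribution given the observed midranks is computed by subset-sum
#' enumeration, so ties are handled exactly; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `x` relative to `y`).
#' @param exact_max_n Largest smaller-sample size for the exact path
#'   (default 25).
#' @return An object of class `"htest"` with the rank-sum statistic `W`,
#'   p-value and method string naming the path taken.
#' @export
#' @examples
#' wilcox_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # exact 0.1
wilcox_rank_sum <- function(x, y,
                            alternative = c("two.sided", "less", "greater"),
                            exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 observations on each side", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  exact <- min(n1, n2) <= exact_max_n

  if (exact) {
    r2 <- as.integer(round(2 * r))
    counts <- subset_sum_counts(r2, n1)
    total <- choose(N, n1)
    w2 <- as.integer(round(2 * W))
    sums <- seq_along(counts) - 1L
    p_le <- sum(counts[sums <= w2]) / total
    p_ge <- sum(counts[sums >= w2]) / total
    method <- "Wilcoxon rank-sum, exact conditional null (midranks)"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p_le <- stats::pnorm((W - mu + 0.5) / sigma)
    p_ge <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    method <- "Wilcoxon rank-sum, normal approximation with continuity correction"
  }
  p <- switch(alternative,
              two.sided = two_sided_p(p_le, p_ge),
              less = p_le, greater = p_ge)
  structure(list(statistic = c(W = W), p.value = p, method = method,
                 alternative = alternative,
                 data.name = sprintf("x (n=%d) vs y (n=%d)", n1, n2)),
            class = "htest")
}

#' Exact/approximate Wilcoxon signed-rank test with midranks
#'
#' One-sample / paired-difference test on `d`. Zero differences are
#' dropped (with a message); V = sum of the (mid)ranks of |d| over the
#' positive differences. For at most `exact_max_n` nonzero differences
#' the exact null is built from the 2^n sign-flip distribution via a
#' generating-function product (ties exact by midranks); otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param d Numeric vector of (paired) differences, >= 2 nonzero values.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max_n Largest n for the exact path (default 25).
#' @return An `"htest"` object with statistic `V` and p-value.
#' @export
#' @examples
#' wilcox_signed_rank(c(2, 1, 3), alternative = "greater")$p.value  # 1/8
wilcox_signed_rank <- function(d,
                               alternative = c("two.sided", "less", "greater"),
                               exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(d)
  nz <- d != 0
  if (any(!nz)) {
    message("dropping ", sum(!nz), " zero difference(s)")
    d <- d[nz]
  }
  n <- length(d)
  if (n < 2L) stop("need at least 2 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  exact <- n <= exact_max_n

  if (exact) {
    r2 <- as.integer(round(2 * r))
    smax <- sum(r2)
    f <- numeric(smax + 1L); f[1L] <- 1
    for (v in r2) {
      g <- f
      idx <- (v + 1L):(smax + 1L)
      g[idx] <- g[idx] + f[seq_len(smax + 1L - v)]
      f <- g
    }
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    sums <- seq_along(f) - 1L
    p_le <- sum(f[sums <= v2]) / total
    p_ge <- sum(f[sums >= v2]) / total
    method <- "Wilcoxon signed-rank, exact null (midranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p_le <- stats::pnorm((V - mu + 0.5) / sigma)
    p_ge <- stats::pnorm((V - mu - 0.5) / sigma, lower.tail = FALSE)
    method <- "Wilcoxon signed-rank, normal approximation with continuity correction"
  }
  p <- switch(alternative,
              two.sided = two_sided_p(p_le, p_ge),
              less = p_le, greater = p_ge)
  structure(list(statistic = c(V = V), p.value = p, method = method,
                 alternative = alternative,
                 data.name = sprintf("%d nonzero differences", n)),
            class = "htest")
}

#' Compare two cohorts' repeat-length distributions
#'
#' Two modes. `"rank_sum"` compares the allele-length multisets (two
#' alleles per sample) of the two cohorts at one named locus — an
#' unpaired comparison of one locus between populations. `"signed_rank"`
#' compares paired per-locus summary values (by default the allele mode)
#' across all loci genotyped in both cohorts — a paired comparison of two
#' populations over a locus panel. Exact null distributions are used for
#' small samples (see [wilcox_rank_sum()] / [wilcox_signed_rank()]).
#'
#' @param a,b Calls data.frames (`sample`, `locus`, `a1`, `a2`).
#' @param locus Locus id (required for `"rank_sum"`; ignored otherwise).
#' @param mode `"rank_sum"` or `"signed_rank"`.
#' @param summary_fun Per-locus summary used in `"signed_rank"` mode
#'   (default the smallest-most-frequent allele, i.e. the mode).
#' @param alternative Passed through to the test.
#' @return An `"htest"` object.
#' @export
compare_cohorts <- function(a, b, locus = NULL,
                            mode = c("rank_sum", "signed_rank"),
                            summary_fun = allele_mode,
                            alternative = "two.sided") {
  mode <- match.arg(mode)
  a <- normalize_calls(a); b <- normalize_calls(b)
  if (mode == "rank_sum") {
    if (is.null(locus)) stop("rank_sum mode needs a locus id", call. = FALSE)
    xa <- a[a$locus == locus, ]; xb <- b[b$locus == locus, ]
    if (nrow(xa) == 0L || nrow(xb) == 0L) {
      stop("locus ", locus, " not genotyped in both cohorts", call. = FALSE)
    }
    ht <- wilcox_rank_sum(c(xa$a1, xa$a2), c(xb$a1, xb$a2),
                          alternative = alternative)
    ht$data.name <- sprintf("allele lengths at %s: cohort a (%d chromosomes) vs b (%d)",
                            locus, 2L * nrow(xa), 2L * nrow(xb))
  } else {
    shared <- intersect(unique(a$locus), unique(b$locus))
    if (length(shared) < 2L) {
      stop("signed_rank mode needs >= 2 loci genotyped in both cohorts",
           call. = FALSE)
    }
    va <- vapply(shared, function(l) {
      summary_fun(c(a$a1[a$locus == l], a$a2[a$locus == l]))
    }, numeric(1))
    vb <- vapply(shared, function(l) {
      summary_fun(c(b$a1[b$locus == l], b$a2[b$locus == l]))
    }, numeric(1))
    ht <- wilcox_signed_rank(va - vb, alternative = alternative)
    ht$data.name <- sprintf("paired per-locus summaries over %d shared loci",
                            length(shared))
  }
  ht
}
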