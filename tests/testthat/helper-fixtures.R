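options(hetstab.quiet = TRUE)

# Two-chromosome toy genome with one pericentromeric interval each.
tiny_genome <- function() {
  genome_model(
    data.frame(chrom = c("c1", "c2"), length = c(1e5, 1e5)),
    data.frame(chrom = c("c1", "c2"), start = c(4e4, 4e4), end = c(6e4, 6e4))
  )
}

make_track <- function(chrom, start, end, value) {
  hetstab:::new_binned_track(tibble::tibble(
    chrom = chrom, start = start, end = end, value = value
  ))
}

# 70 bp toy chromosome with three genes used by the effect classifier tests:
#   G1 (+): single exon [10,19), CDS "ATGTGGTAA"          (1-based 11-19)
#   G2 (+): exons [30,36) and [44,50), CDS "ATGCCC|GGGTAA" (intron [36,44))
#   G3 (-): single exon [54,63), genomic "TTATCGCAT", coding "ATGCGATAA"
toy_sequence <- function() {
  s <- paste0(
    "ACGTACGTAC", # 1-10 filler
    "ATGTGGTAA", # 11-19 G1 CDS
    "CCCCCCCCCCC", # 20-30 filler
    "ATGCCC", # 31-36 G2 exon 1
    "TTTTTTTT", # 37-44 G2 intron
    "GGGTAA", # 45-50 G2 exon 2
    "ACGT", # 51-54 filler
    "TTATCGCAT", # 55-63 G3 (minus strand)
    "ACGTACG" # 64-70 filler
  )
  out <- Biostrings::DNAStringSet(c(cT = s))
  names(out) <- "cT"
  out
}

toy_features <- function() {
  feature_model(tibble::tibble(
    feature_id = c("G1", "G2", "G3"),
    chrom = "cT",
    strand = c("+", "+", "-"),
    class = "gene",
    exons = list(
      tibble::tibble(start = 10, end = 19),
      tibble::tibble(start = c(30, 44), end = c(36, 50)),
      tibble::tibble(start = 54, end = 63)
    ),
    cds = list(
      tibble::tibble(start = 10, end = 19),
      tibble::tibble(start = c(30, 44), end = c(36, 50)),
      tibble::tibble(start = 54, end = 63)
    )
  ))
}

variant_row <- function(chrom, pos, ref, alt, depth = 30, alt_count = 30) {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    depth = depth, alt_count = alt_count,
    mismatch_fraction = alt_count / depth
  )
}

# Benjamini-Hochberg oracle: sort-and-cummin, independent of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  i <- order(p)
  q <- p[i] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[i] <- pmin(q, 1)
  out
}

# One-sided binomial tail by direct pmf summation.
binom_tail_oracle <- function(k, n, eps) {
  if (k > n) return(0)
  sum(stats::dbinom(k:n, n, eps))
}

# Two-sided Fisher p by direct support enumeration (minimum-likelihood rule).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  nn <- c + d
  k <- a + c
  if (m + nn == 0 || k == 0 || k == m + nn) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  sum(probs[probs <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
}
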