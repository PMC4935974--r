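# Independent oracles (brute force / enumeration / closed form) used to
# freeze expected values. These never call the package code paths they
# check.

# Poisson upper tail by direct pmf summation in log space.
oracle_poisson_tail <- function(k, mu) {
  if (k == 0) return(1)
  j <- seq(k, max(k + 2000, ceiling(mu) + 2000))
  sum(exp(j * log(mu) - mu - lgamma(j + 1)))
}

# Hypergeometric overlap P(X >= n_ov) by exhaustive enumeration of all
# draws of size n_b from a background of size n_bg with n_a successes.
oracle_hypergeom <- function(n_ov, n_a, n_b, n_bg) {
  draws <- utils::combn(n_bg, n_b)
  hits <- colSums(draws <= n_a)  # successes are items 1..n_a
  mean(hits >= n_ov)
}

# Two-sided Fisher P for a 2x2 table by enumerating all tables with the
# observed margins; tables with probability <= observed (up to the
# conventional 1 + 1e-7 relative slack) are summed.
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  logp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  p <- exp(vapply(xs, logp, 0))
  sum(p[p <= exp(logp(a)) * (1 + 1e-7)])
}

# Per-nucleotide interval overlap oracle: for each pair of 0-based
# half-open intervals on the same chrom/strand, the overlapping positions.
oracle_overlap_positions <- function(s1, e1, s2, e2) {
  intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L))
}

# A small deterministic annotation used across tests:
#   gA (+, chr1): span [0,1000), exons [0,200)+[800,1000),
#                 5'UTR [0,100), 3'UTR [900,1000)  -> intron [200,800)
#   gB (-, chr1): span [2000,3200), exons [2000,2300)+[2900,3200),
#                 3'UTR [2000,2100), 5'UTR [3100,3200) -> intron [2300,2900)
#   gC (+, chr2): single exon span [0,500), no UTRs, no introns
toy_annotation_records <- function() {
  data.frame(
    gene_id = c(rep("gA", 5), rep("gB", 5), rep("gC", 2)),
    type = c("gene", "exon", "exon", "five_utr", "three_utr",
             "gene", "exon", "exon", "three_utr", "five_utr",
             "gene", "exon"),
    chrom = c(rep("chr1", 10), rep("chr2", 2)),
    start = c(0, 0, 800, 0, 900,
              2000, 2000, 2900, 2000, 3100,
              0, 0),
    end = c(1000, 200, 1000, 100, 1000,
            3200, 2300, 3200, 2100, 3200,
            500, 500),
    strand = c(rep("+", 5), rep("-", 5), rep("+", 2))
  )
}

toy_annotation <- function() build_annotation(toy_annotation_records())

# GRanges helper for 0-based half-open test intervals.
gr <- function(chrom, start, end, strand = "+") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand)
}
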