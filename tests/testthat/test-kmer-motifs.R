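# k-mer counting, enrichment against background clusters, distribution
# comparison, positional histograms and motif presence scans.

test_that("k-mer counting slides windows and skips ambiguous letters", {
  t1 <- count_kmers("GGUA", 4)
  expect_equal(unname(t1$counts["GGUA"]), 1)
  expect_equal(unname(t1$freqs["GGUA"]), 1)
  t2 <- count_kmers("GGGG", 2)
  expect_equal(unname(t2$counts["GG"]), 3)
  t3 <- count_kmers("GGNA", 2)
  expect_equal(unname(t3$counts["GG"]), 1)
  expect_equal(t3$total, 1)  # GN / NA windows skipped
  expect_error(count_kmers(c("ACG", "GG"), 4), "exceeds every sequence")
  # DNA input is transparently treated as RNA
  expect_equal(unname(count_kmers("GGTA", 4)$counts["GGUA"]), 1)
})

test_that("k-mer totals and order invariance hold on random sequences", {
  set.seed(5)
  seqs <- vapply(1:50, function(i)
    paste0(sample(c("A", "C", "G", "U", "N"), sample(10:40, 1), TRUE,
                  prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
  k <- 3
  tab <- count_kmers(seqs, k)
  # oracle: windows with no N, counted per sequence
  expected <- sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    wins <- substring(s, 1:(n - k + 1), k:n)
    sum(!grepl("N", wins, fixed = TRUE))
  }, 0L))
  expect_equal(tab$total, expected)
  expect_equal(sum(tab$freqs), 1, tolerance = 1e-9)
  tab2 <- count_kmers(rev(seqs), k)
  expect_identical(tab$counts, tab2$counts)
})

test_that("percent enrichment and seed flags follow their definitions", {
  real <- count_kmers(c("GGUAAG", "GGUAAG", "ACGUAC"), 6)
  bg <- count_kmers(c("GGUAAG", "ACGUAC", "ACGUAC", "UUUUUU"), 6)
  prof <- kmer_enrichment(real, bg, seed_kmer = "GGUA")
  g <- prof[prof$kmer == "GGUAAG", ]
  # f_real = 2/3, f_bg = 1/4 -> percent = 100*(2/3 - 1/4)/(1/4)
  expect_equal(g$percent_enrichment, 100 * (2 / 3 - 1 / 4) / (1 / 4))
  expect_true(g$contains_seed)
  expect_false(prof$contains_seed[prof$kmer == "ACGUAC"])
  # identity -> 0 percent
  prof0 <- kmer_enrichment(bg, bg)
  expect_true(all(prof0$percent_enrichment[!is.na(prof0$percent_enrichment)]
                  == 0))
  # f_bg = 0 with f_real > 0 is undefined, reported via attribute
  expect_true(is.na(prof$percent_enrichment[prof$kmer == "UUUUUU"]) ||
              prof$f_real[prof$kmer == "UUUUUU"] == 0)
  expect_gte(attr(prof, "undefined"), 0)
  expect_error(kmer_enrichment(count_kmers("ACGUA", 5), bg), "word lengths")
})

test_that("IUPAC degeneracy is honored in seed matching", {
  real <- count_kmers(c("GGUAGU", "GGUGGU"), 6)
  prof <- kmer_enrichment(real, real, seed_kmer = "GURG")  # R = A/G
  expect_true(prof$contains_seed[prof$kmer == "GGUAGU"])
  expect_true(prof$contains_seed[prof$kmer == "GGUGGU"])
  expect_false(prof$contains_seed[prof$kmer == "GGUCGU"])
})

test_that("KS comparison handles identity, disjoint and shifted groups", {
  prof <- data.frame(kmer = paste0("k", 1:6),
                     percent_enrichment = c(1, 2, 3, 1, 2, 3),
                     contains_seed = rep(c(TRUE, FALSE), each = 3))
  r <- compare_distributions(prof)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  prof2 <- data.frame(kmer = paste0("k", 1:6),
                      percent_enrichment = c(10, 11, 12, 0, 1, 2),
                      contains_seed = rep(c(TRUE, FALSE), each = 3))
  expect_equal(compare_distributions(prof2)$statistic, 1)

  expect_error(compare_distributions(
    data.frame(percent_enrichment = 1:3, contains_seed = rep(TRUE, 3))),
    "non-empty")

  # a +50% mean shift for 100 seed-containing of 4,100 k-mers is detected
  # at P < 0.01 in at least 95% of seeded repetitions
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    prof3 <- data.frame(
      kmer = paste0("k", 1:4100),
      percent_enrichment = c(rnorm(100, 50, 20), rnorm(4000, 0, 20)),
      contains_seed = rep(c(TRUE, FALSE), c(100, 4000)))
    compare_distributions(prof3)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("background clusters preserve class and length, deterministically", {
  genome <- make_genome(sim_config(seed = 9, genome = list(n_genes = 15)))
  ann <- genome$annotation
  set.seed(2)
  n <- 40
  starts <- sample(0:(sum(GenomicRanges::width(ann$genes)) - 60), n)
  cl <- gr(as.character(GenomicRanges::seqnames(ann$genes))[1],
           starts, starts + sample(20:60, n, TRUE),
           sample(c("+", "-"), n, TRUE))
  S4Vectors::mcols(cl)$region <- assign_region(cl, ann)
  keepable <- as.character(S4Vectors::mcols(cl)$region) != "unassigned"
  bg <- sample_background_clusters(cl[keepable], ann, seed = 4)
  src <- S4Vectors::mcols(bg)$source
  expect_equal(GenomicRanges::width(bg),
               GenomicRanges::width(cl[keepable])[src])
  expect_equal(as.character(S4Vectors::mcols(bg)$region),
               as.character(S4Vectors::mcols(cl[keepable])$region)[src])
  bg2 <- sample_background_clusters(cl[keepable], ann, seed = 4)
  expect_equal(as.data.frame(bg), as.data.frame(bg2))
  bg3 <- sample_background_clusters(cl[keepable], ann, seed = 5)
  expect_false(identical(as.data.frame(bg), as.data.frame(bg3)))

  # a cluster longer than every interval of its class is skipped
  giant <- gr(as.character(GenomicRanges::seqnames(ann$genes))[1], 0, 999999)
  S4Vectors::mcols(giant)$region <- factor("exon", levels = levels(
    S4Vectors::mcols(cl)$region))
  expect_warning(sample_background_clusters(giant, ann, seed = 1),
                 "skipped")
})

test_that("positional histograms localize and normalize motif matches", {
  # chromosome of A's with the motif planted exactly at two cluster centers
  chr <- strrep("A", 5000)
  motif <- "GGUAAG"
  centers <- c(1500, 3500)
  for (cc in centers) {
    substr(chr, cc, cc + 5) <- "GGTAAG"
  }
  genome_seq <- Biostrings::DNAStringSet(stats::setNames(chr, "c"))
  clusters <- gr("c", centers - 1 - 20, centers - 1 + 20)  # centered windows
  h <- motif_positional_histogram(clusters, genome_seq, motif,
                                  window = 1000, bin = 10)
  expect_equal(attr(h, "n_matches"), 2)
  expect_equal(sum(h$density), 1)
  expect_equal(h$bin_start[which.max(h$count)], 0)

  # motif absent everywhere -> all-zero histogram
  h0 <- motif_positional_histogram(clusters, Biostrings::DNAStringSet(
    stats::setNames(strrep("A", 5000), "c")), motif)
  expect_true(all(h0$count == 0))
  expect_true(all(h0$density == 0))

  # minus-strand cluster: motif planted on the transcript (reverse
  # complement in genome) 30 nt downstream of the center
  chr2 <- strrep("A", 3000)
  center <- 1000
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGTAAG")))
  substr(chr2, center - 30 - 5, center - 30) <- rc
  gs2 <- Biostrings::DNAStringSet(stats::setNames(chr2, "c"))
  clm <- gr("c", center - 1 - 10, center - 1 + 10, "-")
  hm <- motif_positional_histogram(clm, gs2, motif, window = 1000, bin = 10)
  expect_equal(attr(hm, "n_matches"), 1)
  expect_equal(hm$bin_start[hm$count == 1], 30)
})

test_that("uniformly planted motifs give a flat positional histogram", {
  # plant ~10,000 motif instances at uniform offsets around 2,000 centers
  set.seed(11)
  n_cl <- 2000
  win <- 1000
  chrlen <- n_cl * 1100 + 2000
  centers <- seq(1000, by = 1100, length.out = n_cl)
  plant_at <- unlist(lapply(seq_len(n_cl), function(i) {
    off <- sort(sample(seq(-win / 2, win / 2 - 1), 5))
    off <- off[c(TRUE, diff(off) >= 8)]  # avoid overlapping plants
    centers[i] + off
  }))
  chr_str <- Biostrings::replaceAt(
    Biostrings::DNAString(strrep("A", chrlen)),
    at = IRanges::IRanges(plant_at, width = 6),
    value = Biostrings::DNAStringSet(rep("GGTAAG", length(plant_at))))
  gs <- Biostrings::DNAStringSet(stats::setNames(as.character(chr_str), "c"))
  clusters <- gr("c", centers - 1, centers)
  h <- motif_positional_histogram(clusters, gs, "GGUAAG",
                                  window = win, bin = 10)
  expect_gt(attr(h, "n_matches"), 8000)
  gof <- suppressWarnings(stats::chisq.test(h$count))
  expect_gt(gof$p.value, 0.01)
})

test_that("motif presence scans respect region restriction and strand", {
  ann <- toy_annotation()
  chr1 <- strrep("A", 4000)
  # plant GGUAA inside gA's 3' UTR [900,1000)
  substr(chr1, 931, 935) <- "GGTAA"
  gs <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = strrep("A", 1000)))
  got <- scan_motif_presence(ann, gs, "GGUAA", regions = "three_utr")
  expect_true(got$present[got$gene_id == "gA"])
  expect_false(got$present[got$gene_id == "gB"])
  expect_false(got$present[got$gene_id == "gC"])
  # restricting to regions that do not carry the motif -> absent
  got2 <- scan_motif_presence(ann, gs, "GGUAA", regions = "intron")
  expect_false(any(got2$present))
  # minus-strand gene: plant the reverse complement in gB's intron
  chr1b <- strrep("A", 4000)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGTAA")))
  substr(chr1b, 2501, 2505) <- rc
  gsb <- Biostrings::DNAStringSet(c(chr1 = chr1b, chr2 = strrep("A", 1000)))
  got3 <- scan_motif_presence(ann, gsb, "GGUAA", regions = "intron")
  expect_true(got3$present[got3$gene_id == "gB"])
  expect_error(scan_motif_presence(ann, gs, "GGUAA", regions = "bogus"),
               "invalid region")
})
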