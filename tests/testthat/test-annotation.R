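# Gene-model construction, region assignment and region-size accounting.

test_that("build_annotation derives introns, merges exons and validates", {
  ann <- toy_annotation()
  expect_s3_class(ann, "genome_annotation")
  # gA: span [0,1000) minus exons [0,200)+[800,1000) -> intron [200,800)
  intr <- ann$introns[S4Vectors::mcols(ann$introns)$gene_id == "gA"]
  expect_equal(GenomicRanges::start(intr) - 1L, 200)
  expect_equal(GenomicRanges::end(intr), 800)

  # overlapping exon records merge
  rec <- data.frame(gene_id = "g1", type = c("gene", "exon", "exon"),
                    chrom = "c", start = c(0, 0, 50), end = c(200, 100, 150),
                    strand = "+")
  ann2 <- build_annotation(rec)
  expect_equal(length(ann2$exons), 1L)
  expect_equal(GenomicRanges::start(ann2$exons) - 1L, 0)
  expect_equal(GenomicRanges::end(ann2$exons), 150)

  # exon outside the gene span is malformed
  bad <- data.frame(gene_id = "g1", type = c("gene", "exon"),
                    chrom = "c", start = c(0, 1100), end = c(1000, 1200),
                    strand = "+")
  expect_error(build_annotation(bad), "outside gene span")

  # unknown strand
  bad2 <- data.frame(gene_id = "g1", type = "exon", chrom = "c",
                     start = 0, end = 100, strand = "*")
  expect_error(build_annotation(bad2), "strand")

  # UTR outside exon space is malformed
  bad3 <- data.frame(gene_id = "g1", type = c("gene", "exon", "three_utr"),
                     chrom = "c", start = c(0, 0, 300), end = c(1000, 200, 400),
                     strand = "+")
  expect_error(build_annotation(bad3), "UTR outside exon space")
})

test_that("assign_region follows the exon > 3'UTR > 5'UTR > intron priority", {
  ann <- toy_annotation()
  # spanning exon-core and 3'UTR space of gA -> exon wins
  expect_equal(as.character(assign_region(gr("chr1", 850, 950), ann)), "exon")
  # inside gA 3'UTR only
  expect_equal(as.character(assign_region(gr("chr1", 910, 960), ann)),
               "three_utr")
  # inside gA 5'UTR only
  expect_equal(as.character(assign_region(gr("chr1", 10, 60), ann)),
               "five_utr")
  # intronic, 100 nt from the nearest boundary -> proximal
  expect_equal(as.character(assign_region(gr("chr1", 300, 340), ann)),
               "proximal_intron")
  # distance rule at the 500-nt default: gB intron is [2300,2900); a 600-nt
  # intron cannot be distal, so use a wide synthetic gene
  wide <- build_annotation(data.frame(
    gene_id = "gW", type = c("gene", "exon", "exon"), chrom = "w",
    start = c(0, 0, 2200), end = c(2400, 100, 2400), strand = "+"))
  expect_equal(as.character(assign_region(gr("w", 700, 740), wide)),
               "distal_intron")  # 600 nt from both boundaries
  expect_equal(as.character(assign_region(gr("w", 550, 590), wide)),
               "proximal_intron")  # 450 nt from the 5' boundary
  # exactly 500 nt is distal (strict < 500 rule)
  expect_equal(as.character(assign_region(gr("w", 600, 700), wide)),
               "distal_intron")
  # chromosome with no genes
  expect_equal(as.character(assign_region(gr("chrZ", 0, 100), ann)),
               "unassigned")
  # strand mismatch -> unassigned
  expect_equal(as.character(assign_region(gr("chr1", 300, 340, "-"), ann)),
               "unassigned")
})

test_that("region priority promotes to the next class when exons vanish", {
  # cluster overlaps exon-core and UTR; rebuilding without the core exon
  # space promotes it down the priority chain
  full <- build_annotation(data.frame(
    gene_id = "g", type = c("gene", "exon", "three_utr"), chrom = "c",
    start = c(0, 600, 800), end = c(1000, 1000, 1000), strand = "+"))
  cl <- gr("c", 700, 900)
  expect_equal(as.character(assign_region(cl, full)), "exon")
  utr_only <- build_annotation(data.frame(
    gene_id = "g", type = c("gene", "exon", "three_utr"), chrom = "c",
    start = c(0, 800, 800), end = c(1000, 1000, 1000), strand = "+"))
  expect_equal(as.character(assign_region(cl, utr_only)), "three_utr")
  no_utr <- build_annotation(data.frame(
    gene_id = "g", type = c("gene", "exon", "exon"), chrom = "c",
    start = c(0, 0, 1900), end = c(2000, 100, 2000), strand = "+"))
  expect_equal(as.character(assign_region(cl, no_utr)), "distal_intron")
})

test_that("relabeling is idempotent and every cluster gets one label", {
  ann <- toy_annotation()
  set.seed(42)
  cl <- gr("chr1", starts <- sample(0:3100, 50), starts + 40,
           sample(c("+", "-"), 50, TRUE))
  lab1 <- assign_region(cl, ann)
  lab2 <- assign_region(cl, ann)
  expect_identical(lab1, lab2)
  expect_false(anyNA(lab1))
  expect_length(lab1, 50)
})

test_that("region fold enrichment reproduces direct fraction arithmetic", {
  ann <- toy_annotation()
  # F_clip = 0.5 exon / 0.25 3'UTR / 0.25 5'UTR by construction
  cl <- c(gr("chr1", 120, 160), gr("chr2", 10, 50),
          gr("chr1", 920, 960), gr("chr1", 20, 60))
  enr <- region_fold_enrichment(cl, ann)
  expect_equal(sum(enr$f_clip), 1, tolerance = 1e-9)
  expect_equal(sum(enr$f_region), 1, tolerance = 1e-9)
  f_clip_exon <- enr$f_clip[enr$region == "exon"]
  f_region_exon <- enr$f_region[enr$region == "exon"]
  expect_equal(f_clip_exon, 0.5)
  expect_equal(enr$log2_fold[enr$region == "exon"],
               log2(0.5 / f_region_exon))

  # identity: clusters distributed exactly as region sizes -> log2 folds 0
  space <- region_space(ann)
  bp <- vapply(space, function(g) sum(GenomicRanges::width(g)), 0)
  # constructed annotation where exons are exactly 10% of nucleotides
  ann10 <- build_annotation(data.frame(
    gene_id = "g", type = c("gene", "exon", "exon"), chrom = "c",
    start = c(0, 0, 950), end = c(1000, 50, 1000), strand = "+"))
  bp10 <- vapply(region_space(ann10),
                 function(g) sum(GenomicRanges::width(g)), 0)
  expect_equal(unname(bp10["exon"] / sum(bp10)), 0.1)
  enr10 <- region_fold_enrichment(gr("c", 10, 30), ann10)
  expect_equal(enr10$log2_fold[enr10$region == "exon"], log2(1 / 0.1))
})

test_that("enrichment with clusters in a zero-width region class errors", {
  ann10 <- build_annotation(data.frame(
    gene_id = "g", type = c("gene", "exon"), chrom = "c",
    start = c(0, 0), end = c(200, 200), strand = "+"))
  # single-exon gene: no UTR or intron space; an exonic cluster is fine
  expect_silent(region_fold_enrichment(gr("c", 10, 30), ann10))
  # but a cluster carrying a label with no annotated space errors
  cl <- gr("c", 10, 30)
  S4Vectors::mcols(cl)$region <- "three_utr"
  expect_error(region_fold_enrichment(cl, ann10), "undefined enrichment")
})

test_that("interval intersection matches examples and a brute-force oracle", {
  r1 <- intersect_clusters(gr("c", 0, 100), gr("c", 50, 150))
  expect_equal(r1$pairs$start, 50)
  expect_equal(r1$pairs$end, 100)
  # half-open adjacency is not an overlap
  expect_equal(nrow(intersect_clusters(gr("c", 0, 100),
                                       gr("c", 100, 200))$pairs), 0)
  # opposite strands never overlap
  expect_equal(nrow(intersect_clusters(gr("c", 0, 100, "+"),
                                       gr("c", 0, 100, "-"))$pairs), 0)

  # commutativity + per-nucleotide oracle on random instances <= 10 kb
  set.seed(7)
  for (rep in 1:20) {
    s1 <- sample(0:9000, 1); e1 <- s1 + sample(1:800, 1)
    s2 <- sample(0:9000, 1); e2 <- s2 + sample(1:800, 1)
    a <- gr("c", s1, e1); b <- gr("c", s2, e2)
    ab <- intersect_clusters(a, b)$pairs
    ba <- intersect_clusters(b, a)$pairs
    pos <- oracle_overlap_positions(s1, e1, s2, e2)
    expect_equal(nrow(ab), as.integer(length(pos) > 0))
    expect_equal(nrow(ab), nrow(ba))
    if (length(pos) > 0) {
      expect_equal(ab$start, min(pos))
      expect_equal(ab$end, max(pos) + 1L)
      expect_equal(ab$start, ba$start)
    }
  }
})

test_that("mixed chromosome dialects trigger a warning, not an error", {
  expect_warning(intersect_clusters(gr("chr1", 0, 10), gr("1", 0, 10)),
                 "dialect")
})

test_that("gene targets count every overlapped same-strand gene", {
  ann <- toy_annotation()
  expect_equal(gene_targets(gr("chr1", 300, 340), ann), "gA")
  expect_equal(gene_targets(GenomicRanges::GRanges(), ann), character(0))
  # overlapping genes on the same strand are both targeted
  ovl <- build_annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2"),
    type = c("gene", "exon", "gene", "exon"),
    chrom = "c", start = c(0, 0, 500, 500), end = c(1000, 1000, 1500, 1500),
    strand = "+"))
  expect_equal(gene_targets(gr("c", 600, 700), ovl), c("g1", "g2"))
  # strand-mismatched cluster targets nothing
  expect_equal(gene_targets(gr("chr1", 300, 340, "-"), ann), character(0))
})
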