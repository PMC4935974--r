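# Gene-set statistics: DE filtering, hypergeometric overlap, Fisher
# association, paired regression, intron-length comparison, splicing
# filtering and term enrichment.

test_that("DE significance requires both effect size and adjusted P", {
  de <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2_fold_change = c(-1.0, 0.5, 1.0, 0.8),
    adjusted_p = c(0.01, 0.001, 0.2, 0.04))
  s <- significant_genes(de)
  expect_equal(s$down, "a")
  expect_equal(s$up, "d")
  expect_false("b" %in% s$significant)  # 0.5 < log2(1.5)
  expect_false("c" %in% s$significant)  # padj 0.2

  # missing adjusted P excluded with a warning
  de$adjusted_p[1] <- NA
  expect_warning(s2 <- significant_genes(de), "missing adjusted P")
  expect_false("a" %in% s2$significant)

  # monotone in the fold-change threshold
  set.seed(2)
  de3 <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2_fold_change = rnorm(200, 0, 1),
                    adjusted_p = runif(200))
  lo <- significant_genes(de3, lfc_threshold = 0.3)$significant
  hi <- significant_genes(de3, lfc_threshold = 0.9)$significant
  expect_true(all(hi %in% lo))
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  bg <- sprintf("g%02d", 1:10)
  r <- hypergeom_overlap(bg[1:5], bg[1:5], bg)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$p_value, oracle_hypergeom(5, 5, 5, 10), tolerance = 1e-12)

  # A = B = background forces complete overlap, p = 1
  expect_equal(hypergeom_overlap(bg, bg, bg)$p_value, 1)

  # random instances with background <= 15
  set.seed(4)
  for (i in 1:25) {
    n_bg <- sample(5:15, 1)
    bgx <- sprintf("x%02d", 1:n_bg)
    n_a <- sample(1:n_bg, 1); n_b <- sample(1:n_bg, 1)
    a <- sample(bgx, n_a); b <- sample(bgx, n_b)
    got <- hypergeom_overlap(a, b, bgx)$p_value
    # oracle enumerates draws of B with A as items 1..n_a
    bgx_sorted <- c(a, setdiff(bgx, a))
    ov <- length(intersect(a, b))
    expect_equal(got, oracle_hypergeom(ov, n_a, n_b, n_bg),
                 tolerance = 1e-12)
  }

  expect_error(hypergeom_overlap(c("zz"), bg[1:2], bg), "not contained")
})

test_that("Fisher two-sided P matches margin-fixed enumeration", {
  # [[2,0],[0,2]] has two-sided p = 1/3
  expressed <- c("t1", "t2", "n1", "n2")
  r <- fisher_binding_regulation(targets = c("t1", "t2"),
                                 regulated = c("t1", "t2"),
                                 expressed = expressed)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-9)
  expect_equal(r$p_value, oracle_fisher2x2(r$table), tolerance = 1e-9)

  # random tables with N <= 40
  set.seed(6)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    universe <- sprintf("u%02d", 1:n)
    tg <- sample(universe, sample(1:(n - 1), 1))
    rg <- sample(universe, sample(1:(n - 1), 1))
    got <- fisher_binding_regulation(tg, rg, universe)
    expect_equal(got$p_value, oracle_fisher2x2(got$table), tolerance = 1e-9)
  }

  # perfectly coupled binding and regulation in a large universe
  universe <- sprintf("u%04d", 1:1000)
  sub <- sample(universe, 50)
  strong <- fisher_binding_regulation(sub, sub, universe)
  expect_lt(strong$p_value, 1e-10)

  expect_error(fisher_binding_regulation("a", "a", character(0)), "empty")
})

test_that("Fisher P values are approximately uniform under independence", {
  ps <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    universe <- sprintf("u%05d", 1:10000)
    tg <- sample(universe, 2000)
    rg <- sample(universe, 2000)
    fisher_binding_regulation(tg, rg, universe)$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("paired log2-change regression matches constructed relationships", {
  base <- data.frame(gene = sprintf("g%03d", 1:50),
                     log2_fold_change = seq(-2, 2, length.out = 50),
                     adjusted_p = 0.01)
  anti <- base; anti$log2_fold_change <- -base$log2_fold_change
  r <- regress_log2_changes(base, anti)
  expect_equal(r$slope, -1, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  r2 <- regress_log2_changes(base, base)
  expect_equal(r2$slope, 1, tolerance = 1e-9)

  # restriction to the both-significant intersection
  mixed <- base
  mixed$adjusted_p[1:40] <- 0.5
  expect_error(regress_log2_changes(
    mixed[1:42, ], mixed[1:42, ]), "fewer than 3")

  # independent tables: slope P > 0.05 in most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(500 + s)
    a <- data.frame(gene = sprintf("g%03d", 1:100),
                    log2_fold_change = rnorm(100, 0, 1),
                    adjusted_p = 0.01)
    b <- a; b$log2_fold_change <- rnorm(100, 0, 1)
    regress_log2_changes(a, b)$p_value > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("intron-length comparison detects planted length differences", {
  # two-exon genes; set A introns 10x longer than set B
  mk_gene <- function(id, intron_len) {
    data.frame(gene_id = id, type = c("gene", "exon", "exon"), chrom = "c",
               start = c(0, 0, 100 + intron_len),
               end = c(200 + intron_len, 100, 200 + intron_len),
               strand = "+")
  }
  set.seed(12)
  ids_a <- sprintf("a%03d", 1:100); ids_b <- sprintf("b%03d", 1:100)
  recs <- rbind(
    do.call(rbind, lapply(seq_along(ids_a), function(i)
      mk_gene(ids_a[i], round(10000 * runif(1, 0.8, 1.2))))),
    do.call(rbind, lapply(seq_along(ids_b), function(i)
      mk_gene(ids_b[i], round(1000 * runif(1, 0.8, 1.2))))))
  ann <- build_annotation(recs)
  cmp <- compare_intron_lengths(list(down = ids_a, other = ids_b), ann)
  expect_lt(cmp$pairwise$p_value, 1e-6)
  expect_gt(cmp$medians["down"], cmp$medians["other"])

  # identical sets: no difference
  same <- compare_intron_lengths(list(x = ids_a, y = ids_a), ann)
  expect_gt(same$pairwise$p_value, 0.99)

  # single-exon genes only: degenerate, not applicable
  single <- build_annotation(data.frame(
    gene_id = rep(c("s1", "s2"), each = 2),
    type = rep(c("gene", "exon"), 2), chrom = "c",
    start = c(0, 0, 1000, 1000), end = c(500, 500, 1500, 1500),
    strand = "+"))
  deg <- compare_intron_lengths(list(x = "s1", y = "s2"), single)
  expect_false(deg$pairwise$applicable)
  expect_true(is.na(deg$pairwise$p_value))
})

test_that("splicing events are filtered by strict Sep and q thresholds", {
  ev <- data.frame(
    event_id = c("e1", "e2", "e3", "e4", "e5"),
    sep_score = c(0.6, -0.7, 0.5, 0.9, 0.2),
    q_value = c(0.01, 0.04, 0.01, 0.2, 0.01))
  out <- filter_splicing_events(ev)
  expect_equal(out$event_id, c("e1", "e2"))
  expect_equal(out$direction, c("inclusion", "exclusion"))
  # |Sep| = 0.5 exactly is dropped; q >= 0.05 is dropped
  expect_false("e3" %in% out$event_id)
  expect_false("e4" %in% out$event_id)
  expect_error(filter_splicing_events(
    data.frame(event_id = "x", sep_score = 1, q_value = 2)), "q values")
})

test_that("term enrichment ranks the matching term first and controls nulls", {
  bg <- sprintf("g%04d", 1:500)
  set.seed(9)
  terms <- lapply(1:10, function(i) sample(bg, 40))
  names(terms) <- sprintf("T%02d", 1:10)
  res <- geneset_enrichment(terms$T03, terms, bg)
  expect_equal(res$term[1], "T03")
  expect_lt(res$p_value[1], 1e-10)
  # zero-overlap term is never more significant than a matched overlap
  expect_true(all(res$p_value >= res$p_value[1]))

  # null queries rarely produce BH-significant terms
  hits <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    q <- sample(bg, 40)
    any(geneset_enrichment(q, terms, bg)$q_value < 0.05)
  }, TRUE)
  # binomial slack around the 5% FDR target with 50 seeds
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 50))

  expect_error(geneset_enrichment(c("nope"), terms, bg), "not contained")
})
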