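#!/usr/bin/env Rscript

# Stage 6: gene-set statistics connecting binding to regulation.
#
# Significant-gene filtering (|log2FC| >= log2(1.5), padj < 0.05),
# hypergeometric overlap of the two DE tables over the expressed
# background, regression of paired log2 changes on the both-significant
# intersection, Fisher association of binding targets with regulation,
# intron-length comparison of regulated gene sets, splicing-event
# filtering and a toy term-enrichment run.

library(rbpkit)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
de <- simulate_de_tables(cfg)
sig_a <- significant_genes(de$table_a)
sig_b <- significant_genes(de$table_b)
ov <- hypergeom_overlap(sig_a$significant, sig_b$significant, de$background)
message(sprintf(
  "DE overlap: %d of (%d, %d) significant genes over %d expressed; P = %.3g",
  ov$n_overlap, ov$n_a, ov$n_b, ov$n_background, ov$p_value))
reg <- regress_log2_changes(de$table_a, de$table_b)
message(sprintf(
  "paired log2FC regression (both-significant, n = %d): slope %.2f, R^2 %.2f, P = %.3g",
  reg$n_genes, reg$slope, reg$r_squared, reg$p_value))

# binding vs regulation over the simulated genome
genome <- make_genome(cfg)
clip <- simulate_clip_reads(genome, cfg)
clusters <- call_clusters(clip$reads, genome$annotation)
targets <- gene_targets(clusters, genome$annotation)
expressed <- names(genome$annotation$genes)
set.seed(seed)
regulated <- union(sample(targets, min(length(targets), 8)),
                   sample(expressed, 4))
ft <- fisher_binding_regulation(targets, regulated, expressed)
message(sprintf("binding vs regulation Fisher P = %.3g (odds ratio %.1f)",
                ft$p_value, ft$odds_ratio))

# long introns in "down" genes: compare planted long-intron genes vs rest
long <- genome$genes$gene_id[genome$genes$long_intron]
rest <- setdiff(genome$genes$gene_id, long)
il <- compare_intron_lengths(list(down = long, other = rest),
                             genome$annotation)
message(sprintf(
  "intron length (down vs other): medians %.0f vs %.0f nt, rank-sum P = %.3g",
  il$medians["down"], il$medians["other"], il$pairwise$p_value))

# splicing-event filter on a small synthetic Sep-score table
set.seed(seed + 1)
events <- data.frame(
  event_id = sprintf("ev%03d", 1:200),
  sep_score = c(rnorm(180, 0, 0.25), runif(20, -1.5, 1.5)),
  q_value = c(runif(180, 0.05, 1), runif(20, 0, 0.049)))
kept <- filter_splicing_events(events)
write_tsv(kept, file.path(out, "splicing_significant.tsv"))
message(sprintf("splicing filter kept %d/%d events (%d inclusion, %d exclusion)",
                nrow(kept), nrow(events), sum(kept$direction == "inclusion"),
                sum(kept$direction == "exclusion")))

# toy GO-style enrichment: one term matching the shared DE genes
terms <- c(list(shared_term = de$truth$shared),
           lapply(stats::setNames(1:9, sprintf("random_term%d", 1:9)),
                  function(i) sample(de$background, 60)))
go <- geneset_enrichment(intersect(sig_a$significant, sig_b$significant),
                         terms, de$background)
write_tsv(go, file.path(out, "term_enrichment.tsv"))
message(sprintf("top enriched term: %s (q = %.3g)", go$term[1],
                go$q_value[1]))

summary_df <- data.frame(
  statistic = c("de_overlap_p", "regression_slope", "regression_r2",
                "fisher_p", "intron_ranksum_p", "n_splicing_kept",
                "top_term_q"),
  value = c(ov$p_value, reg$slope, reg$r_squared, ft$p_value,
            il$pairwise$p_value, nrow(kept), go$q_value[1]))
write_tsv(summary_df, file.path(out, "geneset_summary.tsv"))
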