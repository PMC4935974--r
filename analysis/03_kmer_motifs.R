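#!/usr/bin/env Rscript

# Stage 3: k-mer motif analysis of the called clusters.
#
# 6mer percent enrichment of cluster sequences against region-matched
# random background clusters, a KS comparison of GGUA-containing vs other
# 6mers, and the positional distribution of the planted motif around
# cluster centers (+/- 500 nt, 10-nt bins).

library(rbpkit)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- make_genome(cfg)
clip <- simulate_clip_reads(genome, cfg)
clusters <- call_clusters(clip$reads, genome$annotation, alpha = 1e-4)

bg <- sample_background_clusters(clusters, genome$annotation,
                                 seed = seed + 1)
real_tab <- count_kmers(rbpkit:::extract_interval_seqs(clusters,
                                                       clip$sequences), 6)
bg_tab <- count_kmers(rbpkit:::extract_interval_seqs(bg, clip$sequences), 6)
profile <- kmer_enrichment(real_tab, bg_tab, seed_kmer = "GGUA")
write_tsv(profile[order(-profile$percent_enrichment), ],
          file.path(out, "kmer_enrichment.tsv"))

topk <- profile$kmer[which.max(profile$percent_enrichment)]
ks <- compare_distributions(profile)
message(sprintf("top enriched 6mer: %s; GGUA-containing vs other 6mers:", topk))
message(sprintf("  KS D = %.3f, P = %.3g (%d vs %d 6mers)", ks$statistic,
                ks$p_value, ks$n_seed, ks$n_other))

hist <- motif_positional_histogram(clusters, clip$sequences, cfg$clip$motif,
                                   window = 1000, bin = 10)
write_tsv(hist, file.path(out, "motif_positional_histogram.tsv"))
message(sprintf("positional histogram: %d matches, peak bin at %+d nt",
                attr(hist, "n_matches"),
                hist$bin_start[which.max(hist$count)]))

presence <- scan_motif_presence(genome$annotation, clip$sequences, "GGUAA",
                                regions = c("three_utr", "intron"))
write_tsv(presence, file.path(out, "motif_presence_by_gene.tsv"))
message(sprintf("GGUAA present in 3'UTR/introns of %d/%d genes",
                sum(presence$present), nrow(presence)))
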