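#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Produces a toy genome with exon/intron/UTR structure (10% of genes carry
# a >= 50 kb intron), CLIP reads drawn over 20 planted GGUAAG-centered
# binding sites, RBNS input/pulldown pools at 0/5/20/80/320 nM, paired
# control/knockdown Actinomycin-D decay courses, and paired DE tables.
# Everything is a pure function of the seed; downstream stages re-derive
# the same objects from the same seed, so this script's outputs are the
# on-disk record of what the analyses consumed.

library(rbpkit)

seed <- 1
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- make_genome(cfg)
clip <- simulate_clip_reads(genome, cfg)

write_gtf(genome$records, file.path(out, "genes.gtf"))
write_bed(clip$reads, file.path(out, "clip_reads.bed"))
write_bed(clip$sites, file.path(out, "sites_truth.bed"))
writeLines(paste0(">", names(clip$sequences), "\n",
                  as.character(clip$sequences)),
           file.path(out, "genome.fa"))

rbns <- simulate_rbns_pool(cfg)
write_fastq(stats::setNames(rbns$input$reads,
                            sprintf("in%06d", seq_along(rbns$input$reads))),
            file.path(out, "rbns_input.fastq"))
for (nm in names(rbns$pulldowns)) {
  rd <- rbns$pulldowns[[nm]]$reads
  write_fastq(stats::setNames(rd, sprintf("pd%s_%06d", nm, seq_along(rd))),
              file.path(out, sprintf("rbns_pulldown_%snM.fastq", nm)))
}

decay <- simulate_decay(cfg)
for (cond in c("control", "knockdown")) {
  tc <- decay[[cond]]
  df <- data.frame(gene = rownames(tc$rpkm), tc$rpkm, check.names = FALSE)
  names(df)[-1] <- paste0("t", tc$times)
  write_tsv(df, file.path(out, sprintf("decay_%s.tsv", cond)))
}
write_tsv(decay$truth, file.path(out, "decay_truth.tsv"))

de <- simulate_de_tables(cfg)
write_tsv(de$table_a, file.path(out, "de_table_a.tsv"))
write_tsv(de$table_b, file.path(out, "de_table_b.tsv"))

message(sprintf(
  "simulated: %d genes (%d with long introns), %d CLIP reads over %d sites,",
  nrow(genome$genes), sum(genome$genes$long_intron),
  length(clip$reads), length(clip$sites)))
message(sprintf(
  "  %d-read RBNS pools at %s nM, %d decay genes, %d-gene DE background",
  cfg$rbns$n_reads, paste(cfg$rbns$concentrations, collapse = "/"),
  cfg$decay$n_genes, cfg$de$n_background))
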