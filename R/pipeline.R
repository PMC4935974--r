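# End-to-end synthetic pipeline driver: validated configuration, staged
# execution in dependency order, TSV/BED/GTF/FASTQ/MEME outputs, and a
# structured JSON manifest (versions, seed, parameters, input checksums,
# per-stage record counts).

#' Pipeline configuration with assay-standard default thresholds
#'
#' Bundles every stage threshold at its standard default: cluster-calling
#' alpha 1e-4 (Bonferroni-corrected), RBNS Z >= 2, decay fit R^2 > 0.6,
#' |log2 half-life change| > 1, |log2 fold change| >= log2(1.5) with
#' adjusted P < 0.05, |Sep score| > 0.5 with q < 0.05, 500-nt
#' proximal-intron boundary, and a 1000-nt / 10-nt positional histogram.
#'
#' @param seed Master seed (also seeds the generators).
#' @param alpha Cluster-calling significance threshold.
#' @param k k-mer word length.
#' @param z_threshold RBNS Z-score significance threshold.
#' @param r2_threshold Decay-fit inclusion threshold on R^2.
#' @param hl_log2_threshold Absolute log2 half-life change for stability
#'   calls.
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param padj_threshold Adjusted-P threshold.
#' @param sep_threshold Absolute Sep-score threshold.
#' @param q_threshold Splicing q-value threshold.
#' @param proximal_distance Proximal/distal intron boundary (nt).
#' @param hist_window,hist_bin Positional-histogram window and bin (nt).
#' @param sim A `sim_config` for the generators.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, alpha = 1e-4, k = 6, z_threshold = 2,
                            r2_threshold = 0.6, hl_log2_threshold = 1,
                            lfc_threshold = log2(1.5),
                            padj_threshold = 0.05, sep_threshold = 0.5,
                            q_threshold = 0.05, proximal_distance = 500,
                            hist_window = 1000, hist_bin = 10,
                            sim = sim_config(seed)) {
  check_prob(alpha, "alpha", 0, 1, open = TRUE)
  check_prob(padj_threshold, "padj_threshold", 0, 1, open = TRUE)
  check_prob(q_threshold, "q_threshold", 0, 1, open = TRUE)
  if (k < 1 || k > 12) stop("k must be in 1..12", call. = FALSE)
  if (r2_threshold < 0 || r2_threshold >= 1) {
    stop("r2_threshold must be in [0, 1)", call. = FALSE)
  }
  if (proximal_distance < 0) stop("proximal_distance must be >= 0",
                                  call. = FALSE)
  if (hist_window < 2 * hist_bin) {
    stop("hist_window must cover at least two bins", call. = FALSE)
  }
  stopifnot(inherits(sim, "sim_config"))
  structure(list(
    seed = seed, alpha = alpha, k = k, z_threshold = z_threshold,
    r2_threshold = r2_threshold, hl_log2_threshold = hl_log2_threshold,
    lfc_threshold = lfc_threshold, padj_threshold = padj_threshold,
    sep_threshold = sep_threshold, q_threshold = q_threshold,
    proximal_distance = proximal_distance, hist_window = hist_window,
    hist_bin = hist_bin, sim = sim
  ), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order on generated data: genome and
#' CLIP simulation, cluster calling, region annotation and enrichment,
#' k-mer enrichment against region-matched background clusters, RBNS
#' concentration selection and logo construction, decay fitting with the
#' shuffled null and stability calls, and the gene-set statistics. Stage
#' outputs are written under `out_dir`; a JSON manifest records the
#' package version, seed, parameters, per-stage counts and output
#' checksums.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  check_prob(config$alpha, "alpha", 0, 1, open = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- list()

  # ---- stage: simulate ----
  genome <- make_genome(config$sim)
  clip <- simulate_clip_reads(genome, config$sim)
  write_gtf(genome$records, file.path(out_dir, "genes.gtf"))
  write_bed(clip$reads, file.path(out_dir, "reads.bed"))
  write_bed(clip$sites, file.path(out_dir, "sites_truth.bed"))
  stages$simulate <- list(
    n_genes = length(genome$annotation$genes),
    n_reads = length(clip$reads),
    n_planted_sites = length(clip$sites))
  say("simulate: %d genes, %d reads, %d planted sites",
      stages$simulate$n_genes, stages$simulate$n_reads,
      stages$simulate$n_planted_sites)

  # ---- stage: call-clusters ----
  clusters <- call_clusters(clip$reads, genome$annotation,
                            alpha = config$alpha,
                            proximal_distance = config$proximal_distance)
  cl_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    name = sprintf("cluster%05d", seq_along(clusters)),
    score = S4Vectors::mcols(clusters)$read_count,
    strand = as.character(GenomicRanges::strand(clusters)),
    gene_id = S4Vectors::mcols(clusters)$gene_id,
    p_transcriptome = S4Vectors::mcols(clusters)$p_transcriptome,
    p_gene = S4Vectors::mcols(clusters)$p_gene,
    region = as.character(S4Vectors::mcols(clusters)$region))
  write_tsv(cl_df, file.path(out_dir, "clusters.tsv"))
  stages$call_clusters <- list(
    n_candidates = attr(clusters, "n_tested"),
    n_significant = length(clusters))
  say("call-clusters: %d candidates, %d significant",
      stages$call_clusters$n_candidates, stages$call_clusters$n_significant)

  # ---- stage: region enrichment ----
  enr <- region_fold_enrichment(clusters, genome$annotation,
                                config$proximal_distance)
  write_tsv(enr, file.path(out_dir, "region_enrichment.tsv"))
  stages$region_enrichment <- list(n_regions = nrow(enr))

  # ---- stage: k-mer enrichment vs background clusters ----
  bg <- sample_background_clusters(clusters, genome$annotation,
                                   seed = config$seed + 1L,
                                   config$proximal_distance)
  real_seq <- extract_interval_seqs(clusters, clip$sequences)
  bg_seq <- extract_interval_seqs(bg, clip$sequences)
  profile <- kmer_enrichment(count_kmers(real_seq, config$k),
                             count_kmers(bg_seq, config$k),
                             seed_kmer = substr(
                               to_rna(config$sim$clip$motif), 1, 4))
  ks <- compare_distributions(profile)
  write_tsv(profile, file.path(out_dir, "kmer_enrichment.tsv"))
  hist <- motif_positional_histogram(clusters, clip$sequences,
                                     config$sim$clip$motif,
                                     window = config$hist_window,
                                     bin = config$hist_bin)
  write_tsv(hist, file.path(out_dir, "motif_positional_histogram.tsv"))
  stages$kmer_enrichment <- list(
    n_background_clusters = length(bg),
    ks_statistic = ks$statistic, ks_p = ks$p_value,
    top_kmer = profile$kmer[which.max(profile$percent_enrichment)])
  say("kmer-enrich: top 6mer %s, seed-vs-other KS P = %.3g",
      stages$kmer_enrichment$top_kmer, ks$p_value)

  # ---- stage: rbns ----
  rbns <- simulate_rbns_pool(config$sim)
  chosen <- select_concentration(rbns$pulldowns, rbns$input, k = config$k)
  rvals <- rbns_r_values(rbns$pulldowns[[as.character(chosen)]],
                         rbns$input, k = config$k,
                         z_threshold = config$z_threshold)
  logos <- build_motif_logos(rbns$pulldowns[[as.character(chosen)]],
                             rbns$input, k = config$k,
                             z_threshold = config$z_threshold)
  write_tsv(rvals[order(-rvals$R), ],
            file.path(out_dir, "rbns_enrichment.tsv"))
  write_pwm_meme(logos, file.path(out_dir, "rbns_logos.meme"))
  stages$rbns <- list(
    chosen_concentration = as.numeric(chosen),
    n_significant_kmers = sum(rvals$significant, na.rm = TRUE),
    n_logos = length(logos$logos),
    top_kmer = rvals$kmer[which.max(rvals$R)])
  say("rbns: chose %g nM, top 6mer %s, %d logo(s)",
      stages$rbns$chosen_concentration, stages$rbns$top_kmer,
      stages$rbns$n_logos)

  # ---- stage: decay ----
  decay <- simulate_decay(config$sim)
  fits_ctrl <- fit_decay_all(decay$control,
                             r2_threshold = config$r2_threshold)
  fits_kd <- fit_decay_all(decay$knockdown,
                           r2_threshold = config$r2_threshold)
  null <- shuffled_null(decay$control, seed = config$seed + 2L,
                        r2_threshold = config$r2_threshold)
  calls <- classify_stability(fits_kd, fits_ctrl,
                              threshold = config$hl_log2_threshold)
  write_tsv(fits_ctrl, file.path(out_dir, "decay_fits_control.tsv"))
  write_tsv(fits_kd, file.path(out_dir, "decay_fits_knockdown.tsv"))
  write_tsv(calls, file.path(out_dir, "stability_calls.tsv"))
  stages$decay <- list(
    n_included_ctrl = sum(fits_ctrl$included),
    n_included_kd = sum(fits_kd$included),
    median_r2_real = null$median_real,
    median_r2_shuffled = null$median_shuffled,
    ks_p = null$ks_p,
    n_stabilized = sum(calls$call == "stabilized", na.rm = TRUE),
    n_destabilized = sum(calls$call == "destabilized", na.rm = TRUE))
  say("decay: median R2 %.2f (real) vs %.2f (shuffled); %d stabilized, %d destabilized",
      null$median_real, null$median_shuffled, stages$decay$n_stabilized,
      stages$decay$n_destabilized)

  # ---- stage: gene-set statistics ----
  det <- simulate_de_tables(config$sim)
  sig_a <- significant_genes(det$table_a, config$lfc_threshold,
                             config$padj_threshold)
  sig_b <- significant_genes(det$table_b, config$lfc_threshold,
                             config$padj_threshold)
  ov <- hypergeom_overlap(sig_a$significant, sig_b$significant,
                          det$background)
  reg <- regress_log2_changes(det$table_a, det$table_b,
                              lfc_threshold = config$lfc_threshold,
                              padj_threshold = config$padj_threshold)
  targets <- gene_targets(clusters, genome$annotation)
  geneset_df <- data.frame(
    statistic = c("overlap_p", "regression_slope", "regression_r2",
                  "regression_p", "n_targets"),
    value = c(ov$p_value, reg$slope, reg$r_squared, reg$p_value,
              length(targets)))
  write_tsv(geneset_df, file.path(out_dir, "geneset_stats.tsv"))
  stages$geneset <- list(
    n_sig_a = length(sig_a$significant), n_sig_b = length(sig_b$significant),
    overlap_p = ov$p_value, regression_slope = reg$slope,
    n_targets = length(targets))
  say("geneset: overlap P = %.3g, regression slope = %.2f",
      ov$p_value, reg$slope)

  # ---- manifest ----
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "rbpkit",
    version = as.character(utils::packageVersion("rbpkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim_parameters = unclass(config$sim),
    stages = stages,
    output_checksums = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$output_checksums) <-
    basename(names(manifest$output_checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    genome = genome, clip = clip, clusters = clusters,
    region_enrichment = enr, kmer_profile = profile, kmer_ks = ks,
    rbns = rbns, rbns_chosen = chosen, rbns_enrichment = rvals,
    logos = logos, decay = decay, fits_ctrl = fits_ctrl,
    fits_kd = fits_kd, decay_null = null, stability = calls,
    de = det, overlap = ov, regression = reg, targets = targets,
    manifest = manifest
  ))
}
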