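# Seeded synthetic-data generators. Each generator is a pure function of
# its configuration and seed, and returns a truth table sufficient to score
# the downstream stage by parameter recovery.

#' Simulation configuration
#'
#' Bundles the generator settings for every pipeline stage. Defaults follow
#' the assay designs the pipeline targets: RBNS pools of randomized 20-mer
#' RNAs at concentrations 0/5/20/80/320 nM with the binding affinity
#' peaking at 80 nM, CLIP read pileups over motif-centered planted sites,
#' and first-order decay time courses with multiplicative log-normal noise.
#'
#' @param seed Master seed.
#' @param genome,clip,rbns,decay,de Named lists overriding individual
#'   defaults of the corresponding block.
#' @return A `sim_config` object (nested list).
#' @export
sim_config <- function(seed = 1, genome = list(), clip = list(),
                       rbns = list(), decay = list(), de = list()) {
  merge_block <- function(defaults, override) {
    bad <- setdiff(names(override), names(defaults))
    if (length(bad) > 0) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    utils::modifyList(defaults, override)
  }
  cfg <- list(
    seed = seed,
    genome = merge_block(list(
      n_genes = 40,
      chrom = "chrS1",
      exons_per_gene = c(2, 5),        # range, sampled per gene
      exon_length = c(150, 300),       # range, nt
      intron_length = c(400, 2000),    # range, nt
      utr5_length = 100,               # nt
      utr3_length = 250,               # nt
      long_intron_fraction = 0.1,      # genes carrying one long intron
      long_intron_length = 50000,      # nt
      intergenic_gap = 500,            # nt
      gc = 0.5                         # background GC content
    ), genome),
    clip = merge_block(list(
      n_reads = 20000,
      read_length = 40,
      n_sites = 20,
      site_width = 50,
      enrichment = 50,                 # extra per-nt sampling weight of sites
      motif = "GGUAAG"
    ), clip),
    rbns = merge_block(list(
      n_reads = 100000,                # per library
      region_length = 20,
      motif = "GGUAAG",
      concentrations = c(0, 5, 20, 80, 320),   # nM
      affinity = c(0, 1, 4, 10, 6)     # per-occurrence weight gain a(c)
    ), rbns),
    decay = merge_block(list(
      n_genes = 500,
      half_life_range = c(3, 7),       # hours; times below span ~2 half-lives
      times = c(0, 2, 4, 6, 8, 10),    # hours after transcription shutoff
      sigma = 0.1,                     # sd of multiplicative log-normal noise
      n0_range = c(5, 500),            # t=0 RPKM, log-uniform
      frac_stabilized = 0.05,
      stabilization_factor = 4,
      frac_destabilized = 0.05,
      destabilization_factor = 0.25
    ), decay),
    de = merge_block(list(
      n_background = 5000,
      n_sig_a = 300,
      n_sig_b = 300,
      overlap_fraction = 0.3,
      correlation_sign = 1,            # sign of shared-gene effect coupling
      lfc_threshold = log2(1.5)
    ), de)
  )
  if (cfg$genome$n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  if (length(cfg$rbns$affinity) != length(cfg$rbns$concentrations)) {
    stop("rbns affinity and concentrations must align", call. = FALSE)
  }
  if (cfg$rbns$affinity[cfg$rbns$concentrations == 0] != 0) {
    stop("the 0 nM (no-protein) library must have affinity 0", call. = FALSE)
  }
  check_prob(cfg$genome$long_intron_fraction, "long_intron_fraction",
             0, 1, open = FALSE)
  check_prob(cfg$de$overlap_fraction, "overlap_fraction", 0, 1, open = FALSE)
  if (any(cfg$rbns$affinity < 0)) stop("affinities must be >= 0",
                                       call. = FALSE)
  if (cfg$decay$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a toy genome: annotation plus chromosome sequence
#'
#' Lays genes end to end on one chromosome (alternating strands) with
#' exon/intron structure, terminal UTRs, and a configurable fraction of
#' genes carrying one long intron (>= `long_intron_length` nt) to exercise
#' long-intron analyses. Sequence is i.i.d. with the configured GC content.
#' Deterministic for a given config and seed.
#'
#' @param config A `sim_config`.
#' @param seed Seed; defaults to the config's master seed.
#' @return List: `annotation` (`genome_annotation`), `sequences` (named
#'   DNAStringSet), `genes` (data.frame with `gene_id`, `strand`,
#'   `long_intron`), `records` (the feature rows used).
#' @export
make_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  with_seed(seed, {
    n_long <- ceiling(g$long_intron_fraction * g$n_genes)
    long_ids <- if (n_long > 0) sample.int(g$n_genes, n_long) else integer(0)
    cursor <- 0L
    rows <- list()
    genes <- list()
    for (i in seq_len(g$n_genes)) {
      id <- sprintf("G%04d", i)
      strand <- if (i %% 2 == 1) "+" else "-"
      n_ex <- sample(seq(g$exons_per_gene[1], g$exons_per_gene[2]), 1)
      ex_len <- sample(seq(g$exon_length[1], g$exon_length[2]), n_ex,
                       replace = TRUE)
      # terminal exons gain the UTR lengths so UTRs sit inside exon space
      if (strand == "+") {
        ex_len[1] <- ex_len[1] + g$utr5_length
        ex_len[n_ex] <- ex_len[n_ex] + g$utr3_length
      } else {
        ex_len[1] <- ex_len[1] + g$utr3_length
        ex_len[n_ex] <- ex_len[n_ex] + g$utr5_length
      }
      in_len <- if (n_ex > 1) {
        sample(seq(g$intron_length[1], g$intron_length[2]), n_ex - 1,
               replace = TRUE)
      } else integer(0)
      if (i %in% long_ids && n_ex > 1) in_len[1] <- g$long_intron_length
      gene_start <- cursor
      pos <- cursor
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        ex_start[e] <- pos; ex_end[e] <- pos + ex_len[e]
        pos <- ex_end[e] + if (e < n_ex) in_len[e] else 0L
      }
      gene_end <- ex_end[n_ex]
      # UTRs at the transcript ends: genomic left block for + 5' UTR, etc.
      if (strand == "+") {
        utr5 <- c(ex_start[1], ex_start[1] + g$utr5_length)
        utr3 <- c(ex_end[n_ex] - g$utr3_length, ex_end[n_ex])
      } else {
        utr3 <- c(ex_start[1], ex_start[1] + g$utr3_length)
        utr5 <- c(ex_end[n_ex] - g$utr5_length, ex_end[n_ex])
      }
      rows[[i]] <- data.frame(
        gene_id = id,
        type = c("gene", rep("exon", n_ex), "five_utr", "three_utr"),
        chrom = g$chrom,
        start = c(gene_start, ex_start, utr5[1], utr3[1]),
        end = c(gene_end, ex_end, utr5[2], utr3[2]),
        strand = strand
      )
      genes[[i]] <- data.frame(gene_id = id, strand = strand,
                               long_intron = i %in% long_ids && n_ex > 1,
                               span_start = gene_start, span_end = gene_end)
      cursor <- gene_end + g$intergenic_gap
    }
    records <- do.call(rbind, rows)
    chrom_len <- cursor
    sequences <- Biostrings::DNAStringSet(
      stats::setNames(random_dna(chrom_len, g$gc), g$chrom))
    list(
      annotation = build_annotation(records),
      sequences = sequences,
      genes = do.call(rbind, genes),
      records = records
    )
  })
}

#' Simulate CLIP reads over planted binding sites
#'
#' Plants `n_sites` non-overlapping sites of `site_width` nt inside gene
#' bodies, writes the binding motif into the chromosome sequence at each
#' site center (sense strand of the host gene), and draws reads from a
#' mixture: per-nucleotide sampling weight 1 across all pre-mRNA, plus
#' `enrichment` extra weight per site nucleotide (reads from the site
#' component are centered within the site). `enrichment = 0` yields the
#' uniform null.
#'
#' @param genome Output of [make_genome()].
#' @param config A `sim_config`.
#' @param seed Seed; defaults to the config's master seed.
#' @return List: `reads` (GRanges), `sites` (GRanges truth table with
#'   `site_id`, `gene_id`), `sequences` (motif-bearing DNAStringSet).
#' @export
simulate_clip_reads <- function(genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$clip
  ann <- genome$annotation
  spans <- ann$genes
  chrom <- as.character(GenomicRanges::seqnames(spans))[1]
  seqs <- genome$sequences
  with_seed(seed, {
    # ---- plant sites (non-overlapping, fully inside a gene span) ----
    sites <- GenomicRanges::GRanges()
    if (cl$n_sites > 0) {
      taken <- IRanges::IRanges()
      tries <- 0
      while (length(sites) < cl$n_sites) {
        tries <- tries + 1
        if (tries > 1000 * cl$n_sites) {
          stop("could not place non-overlapping sites", call. = FALSE)
        }
        gi <- sample.int(length(spans), 1)
        w <- GenomicRanges::width(spans)[gi]
        if (w <= cl$site_width) next
        off <- sample.int(w - cl$site_width, 1)
        ir <- IRanges::IRanges(GenomicRanges::start(spans)[gi] + off - 1L,
                               width = cl$site_width)
        if (length(IRanges::findOverlaps(ir, taken)) > 0) next
        taken <- c(taken, ir)
        s <- GenomicRanges::GRanges(chrom, ir,
                                    strand = GenomicRanges::strand(spans)[gi])
        S4Vectors::mcols(s)$gene_id <- names(spans)[gi]
        sites <- c(sites, s)
      }
      S4Vectors::mcols(sites)$site_id <- sprintf("site%03d",
                                                 seq_along(sites))
      # write the motif into the sequence at each site center (sense strand)
      motif_dna <- to_dna(cl$motif)
      mlen <- nchar(motif_dna)
      centers <- GenomicRanges::start(sites) +
        GenomicRanges::width(sites) %/% 2
      at <- IRanges::IRanges(start = centers - mlen %/% 2, width = mlen)
      minus <- as.character(GenomicRanges::strand(sites)) == "-"
      value <- ifelse(minus,
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(motif_dna))),
                      motif_dna)
      seqs[[chrom]] <- Biostrings::replaceAt(
        seqs[[chrom]], at = at, value = Biostrings::DNAStringSet(value))
    }
    # ---- draw reads ----
    span_w <- GenomicRanges::width(spans)
    bg_weight <- sum(span_w)
    site_weight <- if (length(sites) > 0) {
      cl$enrichment * sum(GenomicRanges::width(sites))
    } else 0
    p_site <- site_weight / (bg_weight + site_weight)
    from_site <- stats::runif(cl$n_reads) < p_site
    n_bg <- sum(!from_site)
    read_start <- integer(cl$n_reads)
    read_strand <- character(cl$n_reads)
    if (n_bg > 0) {
      gi <- sample.int(length(spans), n_bg, replace = TRUE, prob = span_w)
      off <- floor(stats::runif(n_bg) * span_w[gi])
      read_start[!from_site] <- GenomicRanges::start(spans)[gi] + off -
        cl$read_length %/% 2
      read_strand[!from_site] <- as.character(
        GenomicRanges::strand(spans))[gi]
    }
    if (any(from_site)) {
      n_s <- sum(from_site)
      si <- sample.int(length(sites), n_s, replace = TRUE,
                       prob = GenomicRanges::width(sites))
      off <- floor(stats::runif(n_s) * GenomicRanges::width(sites)[si])
      # read centered on a position inside the site
      read_start[from_site] <- GenomicRanges::start(sites)[si] + off -
        cl$read_length %/% 2
      read_strand[from_site] <- as.character(
        GenomicRanges::strand(sites))[si]
    }
    chrom_len <- Biostrings::width(seqs)[[1]]
    read_start <- pmax(1L, pmin(read_start,
                                chrom_len - cl$read_length + 1L))
    reads <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(start = read_start, width = cl$read_length),
      strand = read_strand)
    S4Vectors::mcols(reads)$read_id <- sprintf("r%07d", seq_along(reads))
    list(reads = reads, sites = sites, sequences = seqs)
  })
}

random_rna_reads <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "U"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate RBNS input and pulldown pools
#'
#' The input pool is uniform random RNA of the configured region length.
#' Each pulldown library at concentration c resamples fresh random reads
#' with weight 1 + a(c) x (occurrences of the planted motif, overlapping
#' occurrences counted); a(0 nM) = 0 so the no-protein library matches the
#' input distribution.
#'
#' @param config A `sim_config`.
#' @param seed Seed; defaults to the config's master seed.
#' @return List: `input` (`rbns_library`), `pulldowns` (list of
#'   `rbns_library`, named by concentration), `truth` (motif and affinity
#'   per concentration).
#' @export
simulate_rbns_pool <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rb <- config$rbns
  with_seed(seed, {
    input <- rbns_library(random_rna_reads(rb$n_reads, rb$region_length),
                          concentration = NA_real_)
    pulldowns <- list()
    for (i in seq_along(rb$concentrations)) {
      conc <- rb$concentrations[i]
      a <- rb$affinity[i]
      cand <- random_rna_reads(rb$n_reads, rb$region_length)
      occ <- Biostrings::vcountPattern(to_rna(rb$motif),
                                       Biostrings::RNAStringSet(cand))
      wgt <- 1 + a * occ
      idx <- sample.int(rb$n_reads, rb$n_reads, replace = TRUE, prob = wgt)
      pulldowns[[as.character(conc)]] <- rbns_library(cand[idx],
                                                      concentration = conc)
    }
    list(input = input, pulldowns = pulldowns,
         truth = list(motif = to_rna(rb$motif),
                      affinity = stats::setNames(rb$affinity,
                                                 rb$concentrations)))
  })
}

#' Simulate control and knockdown decay time courses
#'
#' Per gene, a control half-life drawn uniformly from the configured range,
#' t = 0 abundance drawn log-uniformly, and RPKM(t) = N0 exp(-lambda t)
#' times multiplicative log-normal noise exp(N(0, sigma)). Knockdown
#' half-lives are the control half-lives times a planted per-gene factor
#' (1 for most genes; configured fractions are stabilized or destabilized).
#'
#' @param config A `sim_config`.
#' @param seed Seed; defaults to the config's master seed.
#' @return List: `control` and `knockdown` (`expression_timecourse`),
#'   `truth` (data.frame with per-gene half-lives and planted factors).
#' @export
simulate_decay <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$decay
  with_seed(seed, {
    n <- d$n_genes
    genes <- sprintf("D%04d", seq_len(n))
    hl_ctrl <- stats::runif(n, d$half_life_range[1], d$half_life_range[2])
    n0 <- exp(stats::runif(n, log(d$n0_range[1]), log(d$n0_range[2])))
    factor <- rep(1, n)
    n_st <- round(d$frac_stabilized * n)
    n_de <- round(d$frac_destabilized * n)
    picked <- sample.int(n, n_st + n_de)
    factor[picked[seq_len(n_st)]] <- d$stabilization_factor
    if (n_de > 0) factor[picked[n_st + seq_len(n_de)]] <-
        d$destabilization_factor
    hl_kd <- hl_ctrl * factor
    course <- function(hl) {
      lam <- log(2) / hl
      m <- outer(seq_len(n), seq_along(d$times),
                 function(i, j) n0[i] * exp(-lam[i] * d$times[j]))
      if (d$sigma > 0) {
        m <- m * exp(matrix(stats::rnorm(length(m), 0, d$sigma), nrow = n))
      }
      rownames(m) <- genes
      m
    }
    ctrl <- expression_timecourse(course(hl_ctrl), d$times, "control")
    kd <- expression_timecourse(course(hl_kd), d$times, "knockdown")
    list(control = ctrl, knockdown = kd,
         truth = data.frame(gene = genes, half_life_ctrl = hl_ctrl,
                            half_life_kd = hl_kd, factor = factor,
                            n0 = n0))
  })
}

#' Simulate paired differential-expression tables
#'
#' Two DE tables over a shared background with a controlled number of
#' shared significant genes (overlap fraction of the smaller significant
#' set) whose log2 fold changes are coupled with the configured sign.
#'
#' @param config A `sim_config`.
#' @param seed Seed; defaults to the config's master seed.
#' @return List: `table_a`, `table_b` (data.frames gene /
#'   log2_fold_change / adjusted_p), `background`, `truth` (shared and
#'   set-specific significant genes).
#' @export
simulate_de_tables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  de <- config$de
  with_seed(seed, {
    bg <- sprintf("E%05d", seq_len(de$n_background))
    n_shared <- round(de$overlap_fraction * min(de$n_sig_a, de$n_sig_b))
    picked <- sample(bg, de$n_sig_a + de$n_sig_b - n_shared)
    shared <- picked[seq_len(n_shared)]
    a_only <- picked[n_shared + seq_len(de$n_sig_a - n_shared)]
    b_only <- picked[de$n_sig_a + seq_len(de$n_sig_b - n_shared)]
    sig_a <- c(shared, a_only)
    sig_b <- c(shared, b_only)
    thr <- de$lfc_threshold
    draw_effect <- function(n) {
      (thr + abs(stats::rnorm(n, 0.5, 0.4))) * sample(c(-1, 1), n, TRUE)
    }
    lfc_a <- stats::setNames(stats::rnorm(length(bg), 0, 0.15), bg)
    lfc_b <- stats::setNames(stats::rnorm(length(bg), 0, 0.15), bg)
    lfc_a[sig_a] <- draw_effect(length(sig_a))
    lfc_b[b_only] <- draw_effect(length(b_only))
    if (n_shared > 0) {
      coupled <- de$correlation_sign * lfc_a[shared] *
        (1 + stats::rnorm(n_shared, 0, 0.1))
      # keep shared genes significant in B
      small <- abs(coupled) < thr
      coupled[small] <- sign(coupled[small]) * (thr + 0.05)
      lfc_b[shared] <- coupled
    }
    padj <- function(sig) {
      p <- stats::runif(length(bg), 0.05, 1)
      names(p) <- bg
      p[sig] <- stats::runif(length(sig), 0, 0.049)
      p
    }
    table_a <- data.frame(gene = bg, log2_fold_change = unname(lfc_a),
                          adjusted_p = unname(padj(sig_a)))
    table_b <- data.frame(gene = bg, log2_fold_change = unname(lfc_b),
                          adjusted_p = unname(padj(sig_b)))
    list(table_a = table_a, table_b = table_b, background = bg,
         truth = list(shared = shared, a_only = a_only, b_only = b_only))
  })
}
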