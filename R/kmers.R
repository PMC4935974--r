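# k-mer motif analysis of cluster sequences: counting, enrichment against
# region-matched random background clusters, seed-containing vs other
# distribution comparison, positional histograms and motif presence scans.

#' Count k-mers in a set of sequences
#'
#' Sliding-window counts over the RNA alphabet; windows containing
#' non-ACGU letters (e.g. N, or masked positions) are skipped. Frequencies
#' are counts over the total number of counted windows.
#'
#' @param sequences Character vector (RNA or DNA spelling) or XStringSet.
#' @param k Word length (>= 1).
#' @return A `kmer_table`: list with `k`, `counts` (named integer over all
#'   4^k words, U alphabet), `freqs` and `total`.
#' @export
count_kmers <- function(sequences, k) {
  if (length(k) != 1 || k < 1) stop("`k` must be a single integer >= 1",
                                    call. = FALSE)
  k <- as.integer(k)
  set <- if (methods::is(sequences, "RNAStringSet")) {
    sequences
  } else if (methods::is(sequences, "XStringSet")) {
    Biostrings::RNAStringSet(sequences)
  } else {
    Biostrings::RNAStringSet(to_rna(sequences))
  }
  if (length(set) == 0 || max(Biostrings::width(set)) < k) {
    stop("empty k-mer table: k = ", k, " exceeds every sequence length",
         call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(set, width = k, step = 1,
                                                 simplify.as = "collapsed")
  total <- sum(counts)
  if (total == 0) {
    stop("empty k-mer table: no countable windows (all windows contain ",
         "ambiguous letters)", call. = FALSE)
  }
  structure(
    list(k = k, counts = counts, freqs = counts / total, total = total),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, %d windows counted\n", x$k, x$total))
  invisible(x)
}

#' Percent enrichment of k-mers over a background set
#'
#' Per k-mer, 100 x (f_real - f_background) / f_background. Words absent
#' from the background (f_background = 0) have undefined enrichment and are
#' reported as NA; their count is stored in the `undefined` attribute.
#'
#' @param real,background `kmer_table` objects with identical `k`.
#' @param seed_kmer Optional IUPAC word; every k-mer containing it is
#'   flagged in `contains_seed`.
#' @return Data.frame (`enrichment_profile`) with columns `kmer`, `f_real`,
#'   `f_background`, `percent_enrichment` and (when `seed_kmer` is given)
#'   `contains_seed`.
#' @export
kmer_enrichment <- function(real, background, seed_kmer = NULL) {
  stopifnot(inherits(real, "kmer_table"), inherits(background, "kmer_table"))
  if (real$k != background$k) {
    stop("k-mer tables have different word lengths (", real$k, " vs ",
         background$k, ")", call. = FALSE)
  }
  kmers <- names(real$freqs)
  f_real <- unname(real$freqs)
  f_bg <- unname(background$freqs[kmers])
  defined <- f_bg > 0
  pct <- ifelse(defined, 100 * (f_real - f_bg) / f_bg, NA_real_)
  out <- data.frame(kmer = kmers, f_real = f_real, f_background = f_bg,
                    percent_enrichment = pct)
  if (!is.null(seed_kmer)) {
    out$contains_seed <- grepl(iupac_regex(seed_kmer), kmers)
  }
  attr(out, "undefined") <- sum(!defined & f_real > 0)
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Compare enrichment distributions of seed-containing vs other k-mers
#'
#' Two-sample two-sided Kolmogorov-Smirnov test between the percent
#' enrichments of k-mers containing the seed word and all others.
#'
#' @param profile An `enrichment_profile` with a `contains_seed` column.
#' @return List with `statistic` (KS D), `p_value`, `n_seed`, `n_other`.
#' @export
compare_distributions <- function(profile) {
  if (is.null(profile$contains_seed)) {
    stop("profile lacks a `contains_seed` column; pass `seed_kmer` to ",
         "kmer_enrichment()", call. = FALSE)
  }
  ok <- !is.na(profile$percent_enrichment)
  x <- profile$percent_enrichment[ok & profile$contains_seed]
  y <- profile$percent_enrichment[ok & !profile$contains_seed]
  if (length(x) == 0 || length(y) == 0) {
    stop("both seed-containing and other k-mer groups must be non-empty",
         call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_seed = length(x), n_other = length(y))
}

#' Sample region-matched random background clusters
#'
#' For each input cluster, draws one interval of identical length placed
#' uniformly at random within the annotated space of the same region class
#' (any gene, same strand as the hosting interval). Placement is uniform
#' over all valid start positions in the class. Clusters whose class has no
#' interval long enough are skipped with a warning.
#'
#' @param clusters GRanges with a `region` metadata column (else labels are
#'   computed).
#' @param annotation A `genome_annotation`.
#' @param seed Integer seed; identical seeds give identical placements.
#' @param proximal_distance Proximal/distal intron boundary (default 500).
#' @return GRanges of background intervals with metadata `region` and
#'   `source` (index of the originating cluster).
#' @export
sample_background_clusters <- function(clusters, annotation, seed,
                                       proximal_distance = 500) {
  region <- S4Vectors::mcols(clusters)$region
  if (is.null(region)) {
    region <- assign_region(clusters, annotation, proximal_distance)
  }
  region <- as.character(region)
  space <- region_space(annotation, proximal_distance)
  lens <- GenomicRanges::width(clusters)

  with_seed(seed, {
    placed <- vector("list", length(clusters))
    skipped <- integer(0)
    for (i in seq_along(clusters)) {
      cls <- region[i]
      if (!cls %in% names(space)) { skipped <- c(skipped, i); next }
      pool <- space[[cls]]
      ok <- GenomicRanges::width(pool) >= lens[i]
      if (!any(ok)) { skipped <- c(skipped, i); next }
      pool <- pool[ok]
      slots <- GenomicRanges::width(pool) - lens[i] + 1
      j <- sample.int(length(pool), 1, prob = slots)
      off <- sample.int(slots[j], 1) - 1L
      placed[[i]] <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(pool)[j],
        ranges = IRanges::IRanges(start = GenomicRanges::start(pool)[j] + off,
                                  width = lens[i]),
        strand = GenomicRanges::strand(pool)[j],
        region = cls, source = i)
    }
    if (length(skipped) > 0) {
      warning(length(skipped), " cluster(s) skipped: no annotated interval ",
              "of the same region class is long enough", call. = FALSE)
    }
    kept <- placed[!vapply(placed, is.null, TRUE)]
    if (length(kept) == 0) {
      out <- GenomicRanges::GRanges()
      S4Vectors::mcols(out) <- S4Vectors::DataFrame(region = character(0),
                                                    source = integer(0))
      return(out)
    }
    do.call(c, kept)
  })
}

# Sense-strand sequences for a set of intervals from a named chromosome set.
extract_interval_seqs <- function(gr, genome_seq) {
  if (!methods::is(genome_seq, "DNAStringSet")) {
    genome_seq <- Biostrings::DNAStringSet(to_dna(genome_seq))
  }
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                     names(genome_seq))
  if (length(missing) > 0) {
    stop("genome sequence missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(rep("", length(gr)))
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    idx <- which(as.character(GenomicRanges::seqnames(gr)) == chr)
    v <- Biostrings::extractAt(
      genome_seq[[chr]],
      IRanges::IRanges(start = GenomicRanges::start(gr)[idx],
                       end = GenomicRanges::end(gr)[idx]))
    out[idx] <- Biostrings::DNAStringSet(v)
  }
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus)) {
    out[minus] <- Biostrings::reverseComplement(out[minus])
  }
  out
}

#' Positional histogram of motif matches around cluster centers
#'
#' For every cluster, motif match start offsets (transcript orientation,
#' motif start minus cluster center) within +/- `window`/2 are collected
#' from the genomic neighborhood and histogrammed with fixed-width bins
#' (floor division into bins). Density is normalized to the total number of
#' matches. Neighborhoods truncated by a sequence end are counted over the
#' available span.
#'
#' @param clusters GRanges of clusters.
#' @param genome_seq Named DNAStringSet (or coercible) of chromosome
#'   sequences.
#' @param motif IUPAC motif (RNA or DNA spelling).
#' @param window Total window width in nt (default 1000, i.e. +/- 500).
#' @param bin Bin width in nt (default 10).
#' @return Data.frame with `bin_start`, `bin_center`, `count`, `density`;
#'   attributes `n_matches` and `n_clusters`.
#' @export
motif_positional_histogram <- function(clusters, genome_seq, motif,
                                       window = 1000, bin = 10) {
  if (!methods::is(genome_seq, "DNAStringSet")) {
    genome_seq <- Biostrings::DNAStringSet(to_dna(genome_seq))
  }
  half <- window %/% 2
  pat <- Biostrings::DNAString(to_dna(motif))
  offsets <- integer(0)
  chrlens <- stats::setNames(Biostrings::width(genome_seq), names(genome_seq))
  for (i in seq_along(clusters)) {
    chr <- as.character(GenomicRanges::seqnames(clusters)[i])
    if (!chr %in% names(genome_seq)) next
    center <- GenomicRanges::start(clusters)[i] +
      GenomicRanges::width(clusters)[i] %/% 2
    lo <- max(1L, center - half)
    hi <- min(chrlens[[chr]], center + half - 1L)
    if (hi - lo + 1 < length(pat)) next
    win <- Biostrings::subseq(genome_seq[[chr]], start = lo, end = hi)
    minus <- as.character(GenomicRanges::strand(clusters)[i]) == "-"
    if (minus) win <- Biostrings::reverseComplement(win)
    m <- Biostrings::matchPattern(pat, win, fixed = FALSE)
    if (length(m) == 0) next
    j <- IRanges::start(m)
    off <- if (minus) {
      center - (hi - j + 1L)   # transcript-direction offset on minus strand
    } else {
      (lo + j - 1L) - center
    }
    offsets <- c(offsets, off[off >= -half & off < half])
  }
  b_lo <- floor(-half / bin)
  b_hi <- floor((half - 1) / bin)
  bins <- b_lo:b_hi
  counts <- tabulate(findInterval(offsets, bins * bin), nbins = length(bins))
  total <- sum(counts)
  out <- data.frame(
    bin_start = bins * bin,
    bin_center = bins * bin + bin / 2,
    count = counts,
    density = if (total > 0) counts / total else rep(0, length(bins))
  )
  attr(out, "n_matches") <- total
  attr(out, "n_clusters") <- length(clusters)
  out
}

#' Scan gene regions for motif presence
#'
#' Flags each gene TRUE iff the motif matches at least once (sense strand,
#' IUPAC degeneracy honored) within any interval of the requested region
#' classes.
#'
#' @param annotation A `genome_annotation`.
#' @param genome_seq Named DNAStringSet (or coercible).
#' @param motif IUPAC motif (RNA or DNA spelling).
#' @param regions Character vector of region classes: any of `exon`,
#'   `three_utr`, `five_utr`, `intron`, `proximal_intron`, `distal_intron`.
#' @param proximal_distance Proximal/distal intron boundary (default 500).
#' @return Data.frame with `gene_id` and logical `present` for every gene.
#' @export
scan_motif_presence <- function(annotation, genome_seq, motif,
                                regions = c("three_utr", "intron"),
                                proximal_distance = 500) {
  stopifnot(inherits(annotation, "genome_annotation"))
  valid <- c("exon", "three_utr", "five_utr", "intron",
             "proximal_intron", "distal_intron")
  bad <- setdiff(regions, valid)
  if (length(bad) > 0) {
    stop("invalid region class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  space <- region_space(annotation, proximal_distance)
  pick <- list()
  for (r in regions) {
    pick[[r]] <- if (r == "intron") annotation$introns else space[[r]]
  }
  intervals <- do.call(c, unname(pick))
  genes <- names(annotation$genes)
  present <- stats::setNames(rep(FALSE, length(genes)), genes)
  if (length(intervals) > 0) {
    seqs <- extract_interval_seqs(intervals, genome_seq)
    pat <- to_dna(motif)
    nhit <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE)
    hit_genes <- unique(S4Vectors::mcols(intervals)$gene_id[nhit > 0])
    present[hit_genes] <- TRUE
  }
  data.frame(gene_id = genes, present = unname(present), row.names = NULL)
}
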