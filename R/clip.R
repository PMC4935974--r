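# CLIP-seq cluster calling.
#
# Significant read clusters are identified with a Poisson model evaluated at
# two background frequencies: a transcriptome-wide rate (reads per nt over
# all pre-mRNA) and a gene-specific rate (reads per nt of the host
# pre-mRNA). A candidate region is significant only if its read count clears
# a Bonferroni-corrected threshold under both rates.

#' Poisson background rates for cluster calling
#'
#' Computes the transcriptome-wide read frequency (reads overlapping any
#' pre-mRNA span divided by the summed pre-mRNA lengths) and per-gene read
#' frequencies (reads overlapping the gene divided by its span length).
#' Rates are stored as reads per nucleotide so that the Poisson mean of a
#' region is rate x length. Reads spanning two genes count once
#' transcriptome-wide and once per overlapped gene; reads overlapping no
#' gene are excluded. All overlap is strand-matched.
#'
#' @param reads GRanges of non-redundant aligned reads.
#' @param annotation A `genome_annotation`.
#' @return List with `rate_transcriptome` (scalar, reads/nt), `rate_gene`
#'   (named numeric, genes with >= 1 read only), `n_mapped` and
#'   `total_length`.
#' @export
compute_rates <- function(reads, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (length(annotation$genes) == 0) {
    stop("empty annotation: cannot compute rates", call. = FALSE)
  }
  genes <- annotation$genes
  per_gene <- GenomicRanges::countOverlaps(genes, reads, minoverlap = 1L)
  n_mapped <- sum(GenomicRanges::countOverlaps(reads, genes,
                                               minoverlap = 1L) > 0)
  if (n_mapped == 0) {
    stop("no reads overlap any pre-mRNA span", call. = FALSE)
  }
  total_length <- sum(GenomicRanges::width(genes))
  rate_gene <- per_gene[per_gene > 0] / GenomicRanges::width(genes)[per_gene > 0]
  names(rate_gene) <- names(genes)[per_gene > 0]
  list(
    rate_transcriptome = n_mapped / total_length,
    rate_gene = rate_gene,
    n_mapped = n_mapped,
    total_length = total_length
  )
}

#' Candidate cluster regions from read coverage
#'
#' Candidates are the maximal intervals of contiguous non-zero read coverage
#' within each pre-mRNA span (reads trimmed to the span, same strand).
#'
#' @param reads GRanges of reads.
#' @param annotation A `genome_annotation`.
#' @param gene_id Optional single gene id; default all genes.
#' @return GRanges of candidate regions with a `gene_id` metadata column,
#'   sorted by coordinate. Genes without reads contribute nothing.
#' @export
find_candidate_regions <- function(reads, annotation, gene_id = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  if (!is.null(gene_id)) {
    if (!gene_id %in% names(genes)) {
      stop("unknown gene id: ", gene_id, call. = FALSE)
    }
    genes <- genes[gene_id]
  }
  h <- GenomicRanges::findOverlaps(reads, genes, minoverlap = 1L)
  if (length(h) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$gene_id <- character(0)
    return(out)
  }
  trimmed <- GenomicRanges::pintersect(
    GenomicRanges::granges(reads)[S4Vectors::queryHits(h)],
    GenomicRanges::granges(genes)[S4Vectors::subjectHits(h)]
  )
  S4Vectors::mcols(trimmed) <- NULL
  ids <- names(genes)[S4Vectors::subjectHits(h)]
  grl <- GenomicRanges::reduce(S4Vectors::split(trimmed, ids))
  out <- unlist(grl, use.names = FALSE)
  S4Vectors::mcols(out)$gene_id <- rep(names(grl), S4Vectors::elementNROWS(grl))
  out[order(GenomicRanges::seqnames(out), GenomicRanges::start(out),
            GenomicRanges::end(out))]
}

#' Poisson upper-tail probability for a read cluster
#'
#' P(X >= k) for X ~ Poisson(rate x length). Vectorized over all arguments.
#'
#' @param k Observed read count(s), >= 0.
#' @param rate Background frequency in reads per nucleotide, >= 0.
#' @param length Region length in nucleotides, >= 1.
#' @return Upper-tail probabilities; `k = 0` gives 1.
#' @export
poisson_tail <- function(k, rate, length) {
  if (any(k < 0) || any(rate < 0) || any(length < 1)) {
    stop("poisson_tail: need k >= 0, rate >= 0, length >= 1", call. = FALSE)
  }
  stats::ppois(k - 1, lambda = rate * length, lower.tail = FALSE)
}

#' Call significant CLIP clusters
#'
#' For every candidate region the read count k (reads overlapping by >= 1
#' nt) is tested against both the transcriptome-wide and the gene-specific
#' Poisson rates; a cluster is significant iff both upper-tail P values are
#' below `alpha / M`, where M is the total number of candidate regions
#' tested (Bonferroni). Output clusters are coordinate-sorted and annotated
#' with genic region labels.
#'
#' @param reads GRanges of non-redundant reads.
#' @param annotation A `genome_annotation`.
#' @param alpha Family-wise significance threshold (default 1e-4).
#' @param proximal_distance Proximal/distal intron boundary (default 500 nt).
#' @param keep `"significant"` (default) or `"all"` candidates.
#' @return GRanges with metadata columns `gene_id`, `read_count`,
#'   `p_transcriptome`, `p_gene`, `significant` and `region`; attribute
#'   `n_tested` records M.
#' @export
call_clusters <- function(reads, annotation, alpha = 1e-4,
                          proximal_distance = 500,
                          keep = c("significant", "all")) {
  keep <- match.arg(keep)
  check_prob(alpha, "alpha", 0, 1, open = TRUE)
  rates <- compute_rates(reads, annotation)
  cand <- find_candidate_regions(reads, annotation)
  m <- length(cand)
  if (m == 0) {
    S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
      gene_id = character(0), read_count = integer(0),
      p_transcriptome = numeric(0), p_gene = numeric(0),
      significant = logical(0),
      region = factor(character(0), levels = REGION_LEVELS))
    attr(cand, "n_tested") <- 0L
    return(cand)
  }
  k <- GenomicRanges::countOverlaps(cand, reads, minoverlap = 1L)
  len <- GenomicRanges::width(cand)
  ids <- S4Vectors::mcols(cand)$gene_id
  p_trans <- poisson_tail(k, rates$rate_transcriptome, len)
  p_gene <- poisson_tail(k, rates$rate_gene[ids], len)
  cutoff <- alpha / m
  sig <- p_trans < cutoff & p_gene < cutoff
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    gene_id = ids, read_count = as.integer(k),
    p_transcriptome = p_trans, p_gene = unname(p_gene), significant = sig,
    region = assign_region(cand, annotation, proximal_distance))
  out <- if (keep == "significant") cand[sig] else cand
  attr(out, "n_tested") <- m
  out
}
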