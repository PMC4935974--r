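# Gene-model construction and genic-region operations.
#
# Internal interval container is GRanges; all data-frame-facing coordinates
# (annotation records, BED) follow the BED dialect: 0-based, half-open.
# Conversion happens exactly once, at construction / IO boundaries.

REGION_LEVELS <- c("exon", "three_utr", "five_utr",
                   "proximal_intron", "distal_intron", "unassigned")

# records (0-based half-open data.frame) -> GRanges (internal, 1-based closed)
records_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = as.character(df$strand)
  )
}

# Merge intervals per gene, keeping the gene_id metadata column.
merge_by_gene <- function(gr) {
  if (length(gr) == 0) return(gr)
  grl <- S4Vectors::split(gr, S4Vectors::mcols(gr)$gene_id)
  red <- GenomicRanges::reduce(grl)
  out <- unlist(red, use.names = FALSE)
  S4Vectors::mcols(out)$gene_id <- rep(names(red), S4Vectors::elementNROWS(red))
  out
}

empty_gene_granges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$gene_id <- character(0)
  gr
}

#' Build a genome annotation from feature records
#'
#' Assembles per-gene models (exons, UTRs, derived introns) from a flat table
#' of feature records. Introns are derived as the gene-span complement of the
#' merged exons; the "exon" region class used for cluster assignment and
#' region-size accounting is the exonic space minus annotated UTR space, so
#' that the five region classes (exon, 3' UTR, 5' UTR, proximal intron,
#' distal intron) partition each gene body.
#'
#' @param records A data.frame with columns `gene_id`, `type` (one of
#'   `gene`, `exon`, `five_utr`, `three_utr`), `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+` or `-`). A `gene` row per gene is
#'   optional; when absent the span is the range of that gene's features.
#' @return A `genome_annotation` object: a list with elements `genes` (named
#'   GRanges of pre-mRNA spans), `exons` (merged exonic space), `exon_core`
#'   (exonic minus UTR), `five_utr`, `three_utr` and `introns`, each carrying
#'   a `gene_id` metadata column.
#' @export
build_annotation <- function(records) {
  required <- c("gene_id", "type", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("annotation records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$type <- normalize_feature_type(records$type)
  bad_strand <- !records$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("unknown strand value(s): ",
         paste(unique(records$strand[bad_strand]), collapse = ", "),
         call. = FALSE)
  }
  if (any(records$start < 0) || any(records$start >= records$end)) {
    stop("malformed annotation: need 0 <= start < end for every record",
         call. = FALSE)
  }

  by_type <- split(records, records$type)
  gene_ids <- unique(records$gene_id)

  # Gene spans: explicit rows, else range of features per gene.
  spans <- if (!is.null(by_type$gene)) by_type$gene else NULL
  if (!is.null(spans) && anyDuplicated(spans$gene_id)) {
    stop("duplicate gene records for: ",
         paste(unique(spans$gene_id[duplicated(spans$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  span_gr <- if (!is.null(spans)) {
    g <- records_to_granges(spans)
    names(g) <- spans$gene_id
    g
  } else {
    feats <- records_to_granges(records)
    S4Vectors::mcols(feats)$gene_id <- records$gene_id
    grl <- S4Vectors::split(feats, records$gene_id)
    g <- unlist(range(grl), use.names = TRUE)
    g
  }
  span_gr <- span_gr[intersect(gene_ids, names(span_gr))]

  class_gr <- function(type) {
    df <- by_type[[type]]
    if (is.null(df)) return(empty_gene_granges())
    g <- records_to_granges(df)
    S4Vectors::mcols(g)$gene_id <- df$gene_id
    merge_by_gene(g)
  }
  exons <- class_gr("exon")
  five_utr <- class_gr("five_utr")
  three_utr <- class_gr("three_utr")

  check_within_span <- function(gr, what) {
    if (length(gr) == 0) return(invisible())
    ids <- S4Vectors::mcols(gr)$gene_id
    unknown <- setdiff(ids, names(span_gr))
    if (length(unknown) > 0) {
      stop("malformed annotation: ", what, " for unknown gene(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    host <- span_gr[ids]
    inside <- as.character(GenomicRanges::seqnames(gr)) ==
        as.character(GenomicRanges::seqnames(host)) &
      as.character(GenomicRanges::strand(gr)) ==
        as.character(GenomicRanges::strand(host)) &
      GenomicRanges::start(gr) >= GenomicRanges::start(host) &
      GenomicRanges::end(gr) <= GenomicRanges::end(host)
    if (!all(inside)) {
      stop("malformed annotation: ", what, " outside gene span for gene(s): ",
           paste(unique(ids[!inside]), collapse = ", "), call. = FALSE)
    }
    invisible()
  }
  check_within_span(exons, "exon")
  check_within_span(five_utr, "5' UTR")
  check_within_span(three_utr, "3' UTR")

  per_gene <- function(gr, id) gr[S4Vectors::mcols(gr)$gene_id == id]

  intron_list <- list()
  core_list <- list()
  for (id in names(span_gr)) {
    ex <- per_gene(exons, id)
    utr <- c(GenomicRanges::granges(per_gene(five_utr, id)),
             GenomicRanges::granges(per_gene(three_utr, id)))
    # UTR space must lie inside exonic space
    if (length(utr) > 0) {
      out_utr <- GenomicRanges::setdiff(utr, GenomicRanges::granges(ex))
      if (sum(GenomicRanges::width(out_utr)) > 0) {
        stop("malformed annotation: UTR outside exon space for gene ", id,
             call. = FALSE)
      }
    }
    intr <- GenomicRanges::setdiff(GenomicRanges::granges(span_gr[id]),
                                   GenomicRanges::granges(ex))
    core <- GenomicRanges::setdiff(GenomicRanges::granges(ex), utr)
    S4Vectors::mcols(intr)$gene_id <- rep(id, length(intr))
    S4Vectors::mcols(core)$gene_id <- rep(id, length(core))
    intron_list[[id]] <- intr
    core_list[[id]] <- core
  }
  introns <- if (length(intron_list)) {
    do.call(c, unname(intron_list))
  } else {
    empty_gene_granges()
  }
  exon_core <- if (length(core_list)) {
    do.call(c, unname(core_list))
  } else {
    empty_gene_granges()
  }

  structure(
    list(genes = span_gr, exons = exons, exon_core = exon_core,
         five_utr = five_utr, three_utr = three_utr, introns = introns),
    class = "genome_annotation"
  )
}

normalize_feature_type <- function(type) {
  map <- c(
    gene = "gene", exon = "exon",
    five_utr = "five_utr", five_prime_utr = "five_utr",
    `5utr` = "five_utr", utr5 = "five_utr",
    three_utr = "three_utr", three_prime_utr = "three_utr",
    `3utr` = "three_utr", utr3 = "three_utr"
  )
  key <- tolower(as.character(type))
  out <- map[key]
  if (anyNA(out)) {
    stop("unknown feature type(s): ",
         paste(unique(type[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d genes, %d exonic / %d intronic intervals\n",
    length(x$genes), length(x$exons), length(x$introns)))
  invisible(x)
}

#' Per-class genic interval space
#'
#' Splits the annotation into the five disjoint region classes used for
#' cluster assignment and region-size accounting. Intronic space is divided
#' at `proximal_distance` nucleotides from each exon-intron boundary.
#'
#' @param annotation A `genome_annotation`.
#' @param proximal_distance Intronic positions closer than this (nt) to an
#'   exon-intron boundary are proximal (default 500).
#' @return Named list of GRanges: `exon`, `three_utr`, `five_utr`,
#'   `proximal_intron`, `distal_intron`.
#' @export
region_space <- function(annotation, proximal_distance = 500) {
  stopifnot(inherits(annotation, "genome_annotation"))
  intr <- annotation$introns
  if (length(intr) > 0) {
    w <- GenomicRanges::width(intr)
    short <- w <= 2 * proximal_distance
    prox_short <- intr[short]
    long <- intr[!short]
    left <- GenomicRanges::resize(long, width = proximal_distance, fix = "start")
    right <- GenomicRanges::resize(long, width = proximal_distance, fix = "end")
    mid <- GenomicRanges::narrow(long, start = proximal_distance + 1,
                                 end = -(proximal_distance + 1))
    proximal <- c(prox_short, left, right)
    distal <- mid
  } else {
    proximal <- intr
    distal <- intr
  }
  list(
    exon = annotation$exon_core,
    three_utr = annotation$three_utr,
    five_utr = annotation$five_utr,
    proximal_intron = proximal,
    distal_intron = distal
  )
}

#' Assign clusters to genic region classes
#'
#' Iterative priority assignment: a cluster overlapping exonic (non-UTR)
#' space is an exon cluster; otherwise 3' UTR, then 5' UTR; otherwise, if it
#' overlaps intronic space, it is a proximal intron cluster when the distance
#' from its nearest edge to the nearest exon-intron boundary of the host
#' intron is below `proximal_distance`, else distal. Clusters overlapping no
#' gene (same strand) are `unassigned`. All overlap is strand-matched.
#'
#' @param clusters GRanges of clusters.
#' @param annotation A `genome_annotation`.
#' @param proximal_distance Proximal/distal boundary in nt (default 500).
#' @return Factor of region labels, one per cluster, with levels
#'   `r paste(REGION_LEVELS, collapse = ", ")`.
#' @export
assign_region <- function(clusters, annotation, proximal_distance = 500) {
  stopifnot(inherits(annotation, "genome_annotation"))
  n <- length(clusters)
  label <- rep(NA_character_, n)

  overlaps_any <- function(space) {
    GenomicRanges::countOverlaps(clusters, space, minoverlap = 1L) > 0
  }
  label[overlaps_any(annotation$exon_core)] <- "exon"
  todo <- is.na(label)
  label[todo & overlaps_any(annotation$three_utr)] <- "three_utr"
  todo <- is.na(label)
  label[todo & overlaps_any(annotation$five_utr)] <- "five_utr"
  todo <- is.na(label)

  if (any(todo) && length(annotation$introns) > 0) {
    idx <- which(todo)
    h <- GenomicRanges::findOverlaps(clusters[idx], annotation$introns,
                                     minoverlap = 1L)
    if (length(h) > 0) {
      cl <- clusters[idx][S4Vectors::queryHits(h)]
      it <- annotation$introns[S4Vectors::subjectHits(h)]
      d_left <- pmax(GenomicRanges::start(cl) - GenomicRanges::start(it), 0L)
      d_right <- pmax(GenomicRanges::end(it) - GenomicRanges::end(cl), 0L)
      d <- pmin(d_left, d_right)
      dmin <- tapply(d, S4Vectors::queryHits(h), min)
      hit_idx <- idx[as.integer(names(dmin))]
      label[hit_idx] <- ifelse(dmin < proximal_distance,
                               "proximal_intron", "distal_intron")
    }
  }
  label[is.na(label)] <- "unassigned"
  factor(label, levels = REGION_LEVELS)
}

#' Region-size-normalized binding enrichment
#'
#' For each region class, compares the fraction of clusters assigned to the
#' class (F_clip) with the fraction of annotated nucleotides in the class
#' (F_region) as log2(F_clip / F_region).
#'
#' @param clusters GRanges of clusters; region labels are taken from a
#'   `region` metadata column when present, else computed.
#' @param annotation A `genome_annotation`.
#' @param proximal_distance Proximal/distal boundary in nt (default 500).
#' @return A data.frame with one row per region class: `region`,
#'   `n_clusters`, `f_clip`, `region_bp`, `f_region`, `log2_fold`.
#' @export
region_fold_enrichment <- function(clusters, annotation,
                                   proximal_distance = 500) {
  region <- S4Vectors::mcols(clusters)$region
  if (is.null(region)) {
    region <- assign_region(clusters, annotation, proximal_distance)
  }
  region <- factor(as.character(region), levels = REGION_LEVELS)
  assigned <- region[region != "unassigned", drop = FALSE]
  if (length(assigned) == 0) {
    stop("no assigned clusters: cannot compute region enrichment",
         call. = FALSE)
  }
  classes <- setdiff(REGION_LEVELS, "unassigned")
  n_clip <- table(factor(as.character(assigned), levels = classes))
  f_clip <- as.numeric(n_clip) / sum(n_clip)

  space <- region_space(annotation, proximal_distance)
  bp <- vapply(space[classes], function(gr) sum(GenomicRanges::width(gr)), 0)
  if (sum(bp) == 0) stop("annotation has no region space", call. = FALSE)
  f_region <- bp / sum(bp)

  undefined <- f_region == 0 & f_clip > 0
  if (any(undefined)) {
    stop("undefined enrichment: clusters assigned to region(s) with zero ",
         "annotated space: ", paste(classes[undefined], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    region = classes,
    n_clusters = as.integer(n_clip),
    f_clip = f_clip,
    region_bp = as.numeric(bp),
    f_region = f_region,
    log2_fold = log2(f_clip / f_region),
    row.names = NULL
  )
}

#' Strand-aware interval intersection report
#'
#' Reports every same-strand overlapping pair between two interval sets
#' (intersection length >= 1 nt, half-open adjacency is not an overlap)
#' together with the overlapping sub-intervals and per-interval hit flags.
#'
#' @param a,b GRanges.
#' @return List with `pairs` (data.frame: indices into `a` and `b` plus the
#'   overlap sub-interval in 0-based half-open coordinates), `a_overlaps` and
#'   `b_overlaps` (logical flags per input interval).
#' @export
intersect_clusters <- function(a, b) {
  warn_mixed_dialects(a, b)
  h <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L)
  q <- S4Vectors::queryHits(h)
  s <- S4Vectors::subjectHits(h)
  inter <- GenomicRanges::pintersect(GenomicRanges::granges(a)[q],
                                     GenomicRanges::granges(b)[s])
  pairs <- data.frame(
    a = q, b = s,
    chrom = as.character(GenomicRanges::seqnames(inter)),
    start = GenomicRanges::start(inter) - 1L,
    end = GenomicRanges::end(inter),
    strand = as.character(GenomicRanges::strand(inter)),
    width = GenomicRanges::width(inter)
  )
  list(
    pairs = pairs,
    a_overlaps = seq_along(a) %in% q,
    b_overlaps = seq_along(b) %in% s
  )
}

#' Derive target genes from binding clusters
#'
#' A gene is a target iff at least one cluster overlaps its pre-mRNA span on
#' the same strand. Clusters spanning several overlapping genes count toward
#' each of them.
#'
#' @param clusters GRanges of (significant) clusters.
#' @param annotation A `genome_annotation`.
#' @return Sorted character vector of target gene ids.
#' @export
gene_targets <- function(clusters, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (length(clusters) == 0) return(character(0))
  hit <- GenomicRanges::countOverlaps(annotation$genes, clusters,
                                      minoverlap = 1L) > 0
  sort(names(annotation$genes)[hit])
}
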