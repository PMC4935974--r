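# Gene-set statistics connecting binding to regulation: differential
# expression filtering, hypergeometric overlap, Fisher association,
# regression of paired log2 changes, intron-length comparison, splicing
# event filtering and generic (GO-style) gene-set enrichment.

#' Significant differentially expressed genes
#'
#' A gene is significant iff |log2 fold change| >= `lfc_threshold` and
#' adjusted P < `padj_threshold`; significant genes are split by fold-change
#' sign.
#'
#' @param de Data.frame with columns `gene`, `log2_fold_change`,
#'   `adjusted_p`. Genes with missing adjusted P are excluded with a
#'   warning.
#' @param lfc_threshold Absolute log2 fold-change threshold (default
#'   log2(1.5)).
#' @param padj_threshold Adjusted-P threshold (default 0.05, strict).
#' @return List with character vectors `up`, `down` and `significant`.
#' @export
significant_genes <- function(de, lfc_threshold = log2(1.5),
                              padj_threshold = 0.05) {
  if (nrow(de) == 0) stop("empty differential-expression table",
                          call. = FALSE)
  na <- is.na(de$adjusted_p)
  if (any(na)) {
    warning(sum(na), " gene(s) with missing adjusted P excluded",
            call. = FALSE)
    de <- de[!na, ]
  }
  sig <- abs(de$log2_fold_change) >= lfc_threshold &
    de$adjusted_p < padj_threshold
  list(
    up = de$gene[sig & de$log2_fold_change > 0],
    down = de$gene[sig & de$log2_fold_change < 0],
    significant = de$gene[sig]
  )
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability of observing at least the given overlap when
#' `set_b` is drawn from the background with `set_a` as successes.
#'
#' @param set_a,set_b Character vectors; must be subsets of `background`.
#' @param background Character vector: the gene universe (e.g. genes
#'   expressed, RPKM > 1, in the matched control).
#' @return List (`overlap_result`): `n_a`, `n_b`, `n_overlap`,
#'   `n_background`, `p_value`.
#' @export
hypergeom_overlap <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  off <- c(setdiff(set_a, background), setdiff(set_b, background))
  if (length(off) > 0) {
    stop("gene set(s) not contained in background: ",
         paste(utils::head(unique(off), 10), collapse = ", "), call. = FALSE)
  }
  n_a <- length(set_a); n_b <- length(set_b)
  n_bg <- length(background)
  n_ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(n_ov - 1, n_a, n_bg - n_a, n_b, lower.tail = FALSE)
  structure(list(n_a = n_a, n_b = n_b, n_overlap = n_ov,
                 n_background = n_bg, p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of (%d, %d) against %d background; P = %.3g\n",
              x$n_overlap, x$n_a, x$n_b, x$n_background, x$p_value))
  invisible(x)
}

#' Fisher's exact test of binding versus regulation
#'
#' Classifies every expressed gene as target / non-target and regulated /
#' not regulated, and tests the 2x2 association with a two-sided exact test
#' (sum of hypergeometric probabilities at most that of the observed table).
#'
#' @param targets Genes with at least one binding cluster.
#' @param regulated Regulated genes.
#' @param expressed The expressed-gene universe; both sets must be subsets.
#' @return List: `table` (2x2 counts), `p_value`, `odds_ratio`.
#' @export
fisher_binding_regulation <- function(targets, regulated, expressed) {
  expressed <- unique(expressed)
  if (length(expressed) == 0) stop("empty expressed-gene universe",
                                   call. = FALSE)
  targets <- unique(targets); regulated <- unique(regulated)
  off <- c(setdiff(targets, expressed), setdiff(regulated, expressed))
  if (length(off) > 0) {
    stop("gene set(s) not contained in expressed universe: ",
         paste(utils::head(unique(off), 10), collapse = ", "), call. = FALSE)
  }
  is_t <- expressed %in% targets
  is_r <- expressed %in% regulated
  tab <- matrix(c(sum(is_t & is_r), sum(is_t & !is_r),
                  sum(!is_t & is_r), sum(!is_t & !is_r)),
                nrow = 2, byrow = TRUE,
                dimnames = list(target = c("yes", "no"),
                                regulated = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' Regression of paired log2 fold changes
#'
#' Ordinary least squares of table B's log2 fold changes on table A's,
#' optionally restricted to genes significant in both tables.
#'
#' @param table_a,table_b Data.frames with `gene`, `log2_fold_change`,
#'   `adjusted_p`.
#' @param restrict `"both_significant"` (default) or `"all"`.
#' @inheritParams significant_genes
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (two-sided on
#'   the slope), `n_genes`.
#' @export
regress_log2_changes <- function(table_a, table_b,
                                 restrict = c("both_significant", "all"),
                                 lfc_threshold = log2(1.5),
                                 padj_threshold = 0.05) {
  restrict <- match.arg(restrict)
  m <- merge(table_a[, c("gene", "log2_fold_change", "adjusted_p")],
             table_b[, c("gene", "log2_fold_change", "adjusted_p")],
             by = "gene", suffixes = c("_a", "_b"))
  if (restrict == "both_significant") {
    sig_a <- significant_genes(table_a, lfc_threshold, padj_threshold)
    sig_b <- significant_genes(table_b, lfc_threshold, padj_threshold)
    m <- m[m$gene %in% intersect(sig_a$significant, sig_b$significant), ]
  }
  if (nrow(m) < 3) {
    stop("fewer than 3 genes in the restricted intersection", call. = FALSE)
  }
  fit <- stats::lm(log2_fold_change_b ~ log2_fold_change_a, data = m)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
       r_squared = sm$r.squared, p_value = unname(co[2, 4]),
       n_genes = nrow(m))
}

#' Per-gene intron lengths
#'
#' @param annotation A `genome_annotation`.
#' @param stat `"total"` (sum of intron lengths, default) or `"max"`.
#' @return Named numeric vector over all genes; intron-less genes get 0.
#' @export
gene_intron_lengths <- function(annotation, stat = c("total", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(annotation, "genome_annotation"))
  out <- stats::setNames(rep(0, length(annotation$genes)),
                         names(annotation$genes))
  if (length(annotation$introns) > 0) {
    w <- GenomicRanges::width(annotation$introns)
    id <- S4Vectors::mcols(annotation$introns)$gene_id
    agg <- if (stat == "total") tapply(w, id, sum) else tapply(w, id, max)
    out[names(agg)] <- as.numeric(agg)
  }
  out
}

#' Compare intron lengths between gene sets
#'
#' Per-gene statistic is the summed (or maximum) intron length; every pair
#' of sets is compared with a two-sided Wilcoxon rank-sum test. Intron-less
#' genes count as length 0 and are retained. When all lengths in a pair are
#' identical the test is degenerate and reported as not applicable.
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param annotation A `genome_annotation`; every gene must be annotated.
#' @param stat `"total"` (default) or `"max"` intron length per gene.
#' @return List: `lengths` (list of per-set length vectors), `medians`,
#'   `pairwise` (data.frame set_a, set_b, statistic, p_value, applicable).
#' @export
compare_intron_lengths <- function(gene_sets, annotation,
                                   stat = c("total", "max")) {
  stat <- match.arg(stat)
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop("gene_sets must be a named list", call. = FALSE)
  }
  if (any(lengths(gene_sets) == 0)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  all_len <- gene_intron_lengths(annotation, stat)
  missing <- setdiff(unlist(gene_sets), names(all_len))
  if (length(missing) > 0) {
    stop("gene(s) absent from annotation: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  lens <- lapply(gene_sets, function(g) unname(all_len[g]))
  pairs <- utils::combn(names(gene_sets), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    x <- lens[[a]]; y <- lens[[b]]
    if (length(unique(c(x, y))) == 1) {
      return(data.frame(set_a = a, set_b = b, statistic = NA_real_,
                        p_value = NA_real_, applicable = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              alternative = "two.sided"))
    data.frame(set_a = a, set_b = b, statistic = unname(wt$statistic),
               p_value = wt$p.value, applicable = TRUE)
  })
  list(lengths = lens,
       medians = vapply(lens, stats::median, 0),
       pairwise = do.call(rbind, pw))
}

#' Filter splicing events by separation score and q value
#'
#' Keeps events with |Sep score| > `sep_threshold` and q < `q_threshold`
#' (both strict), annotating the direction: positive Sep scores mark exon
#' inclusion, negative ones exclusion.
#'
#' @param events Data.frame with columns `event_id`, `sep_score`, `q_value`
#'   (other columns carried through).
#' @param sep_threshold Absolute Sep-score threshold (default 0.5).
#' @param q_threshold q-value threshold (default 0.05).
#' @return The significant subset, with a `direction` column.
#' @export
filter_splicing_events <- function(events, sep_threshold = 0.5,
                                   q_threshold = 0.05) {
  if (nrow(events) == 0) stop("empty splicing-event table", call. = FALSE)
  if (any(events$q_value < 0 | events$q_value > 1, na.rm = TRUE)) {
    stop("q values must lie in [0, 1]", call. = FALSE)
  }
  keep <- abs(events$sep_score) > sep_threshold &
    events$q_value < q_threshold
  keep[is.na(keep)] <- FALSE
  out <- events[keep, , drop = FALSE]
  out$direction <- ifelse(out$sep_score > 0, "inclusion", "exclusion")
  rownames(out) <- NULL
  out
}

#' Gene-set (GO-style) enrichment of a query set
#'
#' Hypergeometric upper-tail test per term against the expressed background,
#' with Benjamini-Hochberg adjustment across tested terms. Terms empty after
#' intersection with the background are skipped.
#'
#' @param query Character vector, subset of `background`.
#' @param term_map Named list: term -> character vector of genes.
#' @param background Character vector: the expressed-gene universe.
#' @return Data.frame sorted by P: `term`, `n_term`, `n_overlap`,
#'   `p_value`, `q_value`; skipped terms in attribute `skipped`.
#' @export
geneset_enrichment <- function(query, term_map, background) {
  background <- unique(background)
  query <- unique(query)
  if (length(setdiff(query, background)) > 0) {
    stop("query genes not contained in background: ",
         paste(utils::head(setdiff(query, background), 10), collapse = ", "),
         call. = FALSE)
  }
  terms <- lapply(term_map, function(g) intersect(unique(g), background))
  skipped <- names(terms)[lengths(terms) == 0]
  terms <- terms[lengths(terms) > 0]
  if (length(terms) == 0) stop("no non-empty terms", call. = FALSE)
  rows <- lapply(names(terms), function(tm) {
    ov <- hypergeom_overlap(query, terms[[tm]], background)
    data.frame(term = tm, n_term = length(terms[[tm]]),
               n_overlap = ov$n_overlap, p_value = ov$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
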