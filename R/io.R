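# Readers and writers for the external formats the pipeline touches.
# Coordinates: BED is 0-based half-open, GTF is 1-based inclusive; both are
# converted to/from the internal GRanges container exactly once here.
# Readers reject malformed records (with line context) rather than coerce.

#' Read a BED6 file of intervals
#'
#' @param path File path.
#' @return Data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("BED line ", which(nf < 6)[1], " has fewer than 6 columns ",
         "(missing name/score/strand?)", call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad) > 0) {
    stop("BED line ", bad[1], ": invalid coordinates (need 0 <= start < end)",
         call. = FALSE)
  }
  bad_strand <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stop("BED line ", bad_strand[1], ": strand must be '+' or '-'",
         call. = FALSE)
  }
  data.frame(chrom = m[, 1], start = as.integer(start),
             end = as.integer(end), name = m[, 4],
             score = suppressWarnings(as.numeric(m[, 5])), strand = m[, 6])
}

#' Write intervals as BED6
#'
#' @param x GRanges (metadata columns `name`/`score` used when present) or
#'   a data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  if (methods::is(x, "GRanges")) {
    mc <- S4Vectors::mcols(x)
    x <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      name = if (!is.null(mc$name)) mc$name else
        sprintf("iv%05d", seq_along(x)),
      score = if (!is.null(mc$score)) mc$score else 0,
      strand = as.character(GenomicRanges::strand(x))
    )
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                     x$name, format(x$score, trim = TRUE), x$strand), path)
  invisible(path)
}

#' Convert a BED data.frame to GRanges
#'
#' @param bed Data.frame from [read_bed()].
#' @return GRanges with `name` and `score` metadata columns.
#' @export
bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = bed$strand, name = bed$name, score = bed$score)
}

#' Read a GTF-style annotation into feature records
#'
#' Parses the 9-column tab-separated dialect (1-based inclusive
#' coordinates, `gene_id "..."` in the attributes column) and converts to
#' the 0-based half-open record rows accepted by [build_annotation()].
#' Recognized feature types: gene, exon, five_prime_utr/5UTR,
#' three_prime_utr/3UTR (case-insensitive); other rows are skipped.
#'
#' @param path File path.
#' @return Data.frame of feature records.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("GTF line ", which(nf != 9)[1], ": expected 9 tab-separated ",
         "columns, found ", nf[which(nf != 9)[1]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  type_raw <- tolower(m[, 3])
  known <- c(gene = "gene", exon = "exon",
             five_prime_utr = "five_utr", `5utr` = "five_utr",
             utr5 = "five_utr", five_utr = "five_utr",
             three_prime_utr = "three_utr", `3utr` = "three_utr",
             utr3 = "three_utr", three_utr = "three_utr")
  sel <- type_raw %in% names(known)
  if (!any(sel)) stop("no recognized feature rows in ", path, call. = FALSE)
  m <- m[sel, , drop = FALSE]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(!is.finite(start1) | !is.finite(end1) | start1 < 1 |
                 end1 < start1)
  if (length(bad) > 0) {
    stop("GTF feature row ", bad[1], ": invalid 1-based coordinates",
         call. = FALSE)
  }
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
  no_id <- which(gid == m[, 9])
  if (length(no_id) > 0) {
    stop("GTF feature row ", no_id[1], ": attributes lack gene_id",
         call. = FALSE)
  }
  data.frame(
    gene_id = gid,
    type = unname(known[tolower(m[, 3])]),
    chrom = m[, 1],
    start = start1 - 1L,   # GTF 1-based inclusive -> 0-based half-open
    end = end1,
    strand = m[, 7]
  )
}

#' Write annotation feature records as GTF
#'
#' @param records Data.frame of 0-based half-open feature records (as
#'   accepted by [build_annotation()]).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(records, path, source = "rbpkit") {
  type_out <- c(gene = "gene", exon = "exon",
                five_utr = "five_prime_utr", three_utr = "three_prime_utr")
  writeLines(sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    records$chrom, source, type_out[records$type],
    records$start + 1L, records$end, records$strand, records$gene_id), path)
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' Strict 4-line records; qualities are ignored (the pipeline never uses
#' them).
#'
#' @param path File path.
#' @return Character vector of sequences named by read id.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4",
         call. = FALSE)
  }
  n <- length(lines) / 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  if (any(!startsWith(hdr, "@"))) {
    stop("FASTQ record ", which(!startsWith(hdr, "@"))[1],
         ": header does not start with '@'", call. = FALSE)
  }
  if (any(!startsWith(plus, "+"))) {
    stop("FASTQ record ", which(!startsWith(plus, "+"))[1],
         ": separator line does not start with '+'", call. = FALSE)
  }
  seqs <- lines[seq(2, length(lines), by = 4)]
  names(seqs) <- sub("^@", "", sub(" .*", "", hdr))
  seqs
}

#' Write sequences as FASTQ
#'
#' Constant (uninformative) quality strings.
#'
#' @param seqs Character vector of sequences (names used as read ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(seqs, path) {
  ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("read%07d", seq_along(seqs))
  rec <- sprintf("@%s\n%s\n+\n%s", ids, seqs,
                 vapply(nchar(seqs),
                        function(n) strrep("I", n), ""))
  writeLines(rec, path)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read an expression time-course matrix
#'
#' TSV with a `gene` column and one column per time point; duplicated gene
#' ids are rejected.
#'
#' @param path File path.
#' @param times Numeric vector of hours, one per non-gene column.
#' @param condition Condition label.
#' @return An `expression_timecourse`.
#' @export
read_expression_matrix <- function(path, times, condition = "control") {
  df <- read_tsv_checked(path, "gene", "expression")
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0) {
    stop("duplicated gene id(s) in expression table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric",
                           call. = FALSE)
  rownames(m) <- df$gene
  expression_timecourse(m, times, condition)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `log2_fold_change` (alias `log2FoldChange`,
#' `log2fc`) and `adjusted_p` (alias `padj`).
#'
#' @param path File path.
#' @return Data.frame with the canonical column names.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  alias <- c(log2FoldChange = "log2_fold_change", log2fc = "log2_fold_change",
             padj = "adjusted_p", p_adj = "adjusted_p")
  for (a in names(alias)) {
    if (a %in% names(df) && !alias[[a]] %in% names(df)) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  need <- c("gene", "log2_fold_change", "adjusted_p")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("differential-expression table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$adjusted_p < 0 | df$adjusted_p > 1, na.rm = TRUE)) {
    stop("adjusted P values must lie in [0, 1]", call. = FALSE)
  }
  df[, need]
}

#' Read a splicing-event table
#'
#' TSV with columns `event_id`, `sep_score`, `q_value` (an `event_type`
#' column is carried through when present).
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_splicing_table <- function(path) {
  df <- read_tsv_checked(path, c("event_id", "sep_score", "q_value"),
                         "splicing-event")
  if (any(df$q_value < 0 | df$q_value > 1, na.rm = TRUE)) {
    stop("q values must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Write motif logos as MEME-minimal position frequency matrices
#'
#' @param logo_set A `motif_logo_set` from [build_motif_logos()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwm_meme <- function(logo_set, path) {
  stopifnot(inherits(logo_set, "motif_logo_set"))
  out <- c("MEME version 4", "", "ALPHABET= ACGU", "",
           "strands: +", "")
  for (i in seq_along(logo_set$logos)) {
    lg <- logo_set$logos[[i]]
    out <- c(out,
             sprintf("MOTIF logo%d %s", i, lg$seed),
             sprintf(
               "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
               ncol(lg$pwm), nrow(lg$aligned_kmers)),
             apply(lg$pwm, 2, function(col)
               paste(sprintf("%.6f", col), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
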