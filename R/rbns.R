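# RNA Bind-n-Seq analysis: per-6mer enrichment (R) over the input pool,
# Z-score significance over all 4^k words, concentration selection, and the
# iterative mask-and-align construction of weighted motif logos.

#' Construct an RBNS library
#'
#' @param reads Character vector of random-region sequences (RNA or DNA
#'   spelling); constant flanking primers must already be removed so k-mer
#'   counting is restricted to the random region.
#' @param concentration Protein concentration in nM (`NA` for the input
#'   pool).
#' @return An `rbns_library` object.
#' @export
rbns_library <- function(reads, concentration = NA_real_) {
  reads <- to_rna(reads)
  if (length(reads) == 0) stop("empty read set", call. = FALSE)
  widths <- unique(nchar(reads))
  if (length(widths) != 1) {
    stop("random-region length must be constant; found lengths: ",
         paste(utils::head(widths), collapse = ", "), call. = FALSE)
  }
  if (!is.na(concentration) && concentration < 0) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  structure(list(reads = reads, concentration = concentration,
                 region_length = widths),
            class = "rbns_library")
}

#' @export
print.rbns_library <- function(x, ...) {
  cat(sprintf("rbns_library: %d reads of %d nt, concentration %s nM\n",
              length(x$reads), x$region_length,
              ifelse(is.na(x$concentration), "input",
                     format(x$concentration))))
  invisible(x)
}

.library_reads <- function(x) {
  if (inherits(x, "rbns_library")) x$reads else to_rna(x)
}

# RNAStringSet view of a library / read vector (fast path for the logo loop)
.as_rna_set <- function(x) {
  if (methods::is(x, "RNAStringSet")) return(x)
  Biostrings::RNAStringSet(.library_reads(x))
}

# Mask every (possibly overlapping) occurrence of `word` with N, in place on
# an RNAStringSet; the union of overlapping occurrences is masked.
.mask_set <- function(set, word) {
  m <- Biostrings::vmatchPattern(word, set, fixed = TRUE)
  ir <- IRanges::reduce(methods::as(m, "CompressedIRangesList"))
  if (sum(S4Vectors::elementNROWS(ir)) == 0) return(set)
  val <- IRanges::relist(strrep("N", IRanges::width(unlist(ir))), ir)
  Biostrings::replaceAt(set, at = ir, value = val)
}

# Enrichment from two precomputed kmer_tables (shared core of rbns_r_values)
.rbns_enrichment <- function(tp, ti, z_threshold = 2) {
  kmers <- names(ti$counts)
  f_in <- unname(ti$freqs)
  f_pd <- unname(tp$freqs[kmers])
  defined <- f_in > 0
  r <- ifelse(defined, f_pd / f_in, NA_real_)
  rd <- r[defined]
  mu <- mean(rd)
  sd_pop <- sqrt(mean((rd - mu)^2))
  z <- rep(NA_real_, length(r))
  z[defined] <- if (sd_pop > 0) (rd - mu) / sd_pop else 0
  out <- data.frame(
    kmer = kmers,
    count_input = unname(ti$counts),
    count_pulldown = unname(tp$counts[kmers]),
    f_input = f_in, f_pulldown = f_pd,
    R = r, Z = z,
    significant = !is.na(z) & z >= z_threshold
  )
  attr(out, "excluded") <- kmers[!defined]
  attr(out, "mean_R") <- mu
  attr(out, "sd_R") <- sd_pop
  class(out) <- c("rbns_enrichment", "data.frame")
  out
}

#' RBNS k-mer enrichment (R values) and Z-scores
#'
#' R per k-mer is its frequency in the protein-selected (pulldown) pool over
#' its frequency in the input pool. Z-scores standardize R over all defined
#' k-mers (population standard deviation); a k-mer is significant when
#' Z >= `z_threshold`. Words absent from the input pool have undefined R
#' and are excluded (reported in the `excluded` attribute).
#'
#' @param pulldown,input `rbns_library` objects or character read vectors.
#' @param k Word length (default 6).
#' @param z_threshold Significance threshold on Z (default 2).
#' @return Data.frame (`rbns_enrichment`) with one row per k-mer:
#'   `kmer`, `count_input`, `count_pulldown`, `f_input`, `f_pulldown`, `R`,
#'   `Z`, `significant`. Rows with undefined R carry NA.
#' @export
rbns_r_values <- function(pulldown, input, k = 6, z_threshold = 2) {
  tp <- count_kmers(.as_rna_set(pulldown), k)
  ti <- count_kmers(.as_rna_set(input), k)
  .rbns_enrichment(tp, ti, z_threshold)
}

#' Select the protein concentration with the highest overall enrichment
#'
#' Overall enrichment of a library is its maximum single k-mer R value; the
#' concentration maximizing it is returned, ties broken toward the lower
#' concentration. The 0 nM (no-protein) library is not eligible.
#'
#' @param libraries List of `rbns_library` pulldowns at different
#'   concentrations.
#' @param input Input-pool `rbns_library` (or read vector).
#' @param k Word length (default 6).
#' @return The chosen concentration (nM), with the per-concentration
#'   overall enrichments in attribute `overall`.
#' @export
select_concentration <- function(libraries, input, k = 6) {
  conc <- vapply(libraries, function(l) l$concentration, 0)
  eligible <- which(!is.na(conc) & conc > 0)
  if (length(eligible) == 0) {
    stop("need at least one library with concentration > 0", call. = FALSE)
  }
  overall <- vapply(eligible, function(i) {
    enr <- rbns_r_values(libraries[[i]], input, k = k)
    max(enr$R, na.rm = TRUE)
  }, 0)
  names(overall) <- conc[eligible]
  best <- which(overall == max(overall))
  chosen <- min(conc[eligible][best])
  attr(chosen, "overall") <- overall
  chosen
}

#' Mask all occurrences of a word in a read set
#'
#' Every (possibly overlapping) occurrence is replaced by `N`, excluding the
#' covered positions from all future k-mer windows. The union of overlapping
#' occurrences is masked.
#'
#' @param reads Character vector of reads (RNA or DNA spelling).
#' @param word Word to mask (exact match).
#' @return Character vector of masked reads.
#' @export
mask_occurrences <- function(reads, word) {
  out <- .mask_set(Biostrings::RNAStringSet(to_rna(reads)), to_rna(word))
  as.character(out)
}

# Best alignment of `word` to `seed` over offsets -max_offset..max_offset;
# mismatches counted on overlapping positions only (overhangs ignored).
align_to_seed <- function(seed, word, max_offset = 5) {
  k <- nchar(seed)
  s <- strsplit(seed, "", fixed = TRUE)[[1]]
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  offs <- seq(-max_offset, max_offset)
  offs <- offs[order(abs(offs), offs)]
  best <- list(offset = 0L, mismatches = Inf)
  for (o in offs) {
    i <- seq(max(1, 1 + o), min(k, k + o))   # seed positions in the overlap
    if (length(i) == 0) next
    mm <- sum(s[i] != w[i - o])
    if (mm < best$mismatches) best <- list(offset = as.integer(o),
                                           mismatches = mm)
  }
  best
}

#' Build RBNS motif logos by iterative masking and alignment
#'
#' Iterates: take the k-mer with the highest R; if its Z-score is below
#' `z_threshold`, stop. Otherwise record it with weight R - 1, mask all its
#' occurrences in both the pulldown and input read sets, and recompute all
#' enrichments on the masked sets.
#'
#' Membership in the procedure is decided once: the candidate set is the
#' k-mers with Z >= `z_threshold` in the initial (unmasked) enrichment,
#' the same rule that defines R-value significance. The masking iteration
#' then orders those candidates by their masked-recomputed R and assigns
#' their weights; it ends when no candidate remains or the best remaining
#' candidate's recomputed enrichment has fallen to R <= 1 (such k-mers
#' would carry non-positive weight, their apparent enrichment being fully
#' explained by already-masked words). Re-testing significance against the
#' masked R distribution itself would never terminate on featureless data:
#' the maximum of ~4^k standardized enrichments always exceeds 2 s.d. of
#' whatever distribution remains, so the loop would consume nearly the
#' whole k-mer space. Each accepted k-mer is aligned (offset
#' minimizing mismatches, overhangs ignored) to the seed k-mer of an
#' existing logo and joins it if the minimum mismatch count is at most
#' `max_mismatch`; otherwise it seeds a new logo. Position weight matrix
#' columns are the weight-weighted nucleotide frequencies of the aligned
#' k-mers; each logo's proportion is its share of the summed weights.
#'
#' @param pulldown,input `rbns_library` objects or character read vectors.
#' @param k Word length (default 6).
#' @param z_threshold Stop when the top R's Z-score falls below this
#'   (default 2).
#' @param max_mismatch Maximum mismatches for joining a logo (default 2).
#' @param max_offset Alignment offset range (default 5).
#' @param max_iter Safety guard on iterations (default 4096).
#' @return A `motif_logo_set`: list with `logos` (each a `motif_logo` with
#'   `seed`, `aligned_kmers`, `pwm` (4 x L, columns sum to 1), `proportion`),
#'   `accepted` (acceptance-order data.frame) and `n_iterations`.
#' @export
build_motif_logos <- function(pulldown, input, k = 6, z_threshold = 2,
                              max_mismatch = 2, max_offset = 5,
                              max_iter = 4096) {
  pd <- .as_rna_set(pulldown)
  inp <- .as_rna_set(input)
  enr0 <- rbns_r_values(pd, inp, k = k, z_threshold = z_threshold)
  candidates <- enr0$kmer[enr0$significant]
  logos <- list()
  accepted <- data.frame(kmer = character(0), weight = numeric(0),
                         logo = integer(0), offset = integer(0))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("logo construction did not terminate within ", max_iter,
           " iterations", call. = FALSE)
    }
    if (length(candidates) == 0) break
    enr <- if (iter == 1L) enr0 else {
      tryCatch(.rbns_enrichment(count_kmers(pd, k), count_kmers(inp, k),
                                z_threshold),
               error = function(e) NULL)
    }
    if (is.null(enr)) break
    cur <- enr[match(candidates, enr$kmer), ]
    if (all(is.na(cur$R))) break
    top <- which.max(cur$R)
    word <- cur$kmer[top]
    weight <- cur$R[top] - 1
    if (is.na(weight) || weight <= 0) break
    candidates <- setdiff(candidates, word)

    if (length(logos) == 0) {
      logo_idx <- 1L; offset <- 0L
      logos[[1]] <- list(seed = word,
                         members = data.frame(kmer = word, offset = 0L,
                                              weight = weight))
    } else {
      fits <- lapply(logos, function(lg)
        align_to_seed(lg$seed, word, max_offset))
      mms <- vapply(fits, function(f) f$mismatches, 0)
      best <- which.min(mms)
      if (mms[best] <= max_mismatch) {
        logo_idx <- best
        offset <- fits[[best]]$offset
        logos[[best]]$members <- rbind(
          logos[[best]]$members,
          data.frame(kmer = word, offset = offset, weight = weight))
      } else {
        logo_idx <- length(logos) + 1L; offset <- 0L
        logos[[logo_idx]] <- list(seed = word,
                                  members = data.frame(kmer = word,
                                                       offset = 0L,
                                                       weight = weight))
      }
    }
    accepted <- rbind(accepted,
                      data.frame(kmer = word, weight = weight,
                                 logo = logo_idx, offset = offset))
    pd <- .mask_set(pd, word)
    inp <- .mask_set(inp, word)
  }

  total_weight <- sum(accepted$weight)
  logos <- lapply(logos, function(lg) {
    m <- lg$members
    pos_min <- min(m$offset)
    pos_max <- max(m$offset) + k - 1L
    L <- pos_max - pos_min + 1L
    pwm <- matrix(0, nrow = 4, ncol = L,
                  dimnames = list(c("A", "C", "G", "U"), NULL))
    for (r in seq_len(nrow(m))) {
      letters <- strsplit(m$kmer[r], "", fixed = TRUE)[[1]]
      cols <- m$offset[r] - pos_min + seq_len(k)
      for (j in seq_len(k)) {
        pwm[letters[j], cols[j]] <- pwm[letters[j], cols[j]] + m$weight[r]
      }
    }
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    structure(list(seed = lg$seed, aligned_kmers = m, pwm = pwm,
                   proportion = sum(m$weight) / total_weight),
              class = "motif_logo")
  })
  structure(list(logos = logos, accepted = accepted,
                 n_iterations = iter - 1L, initial = enr0),
            class = "motif_logo_set")
}

#' @export
print.motif_logo_set <- function(x, ...) {
  cat(sprintf("motif_logo_set: %d logo(s) from %d accepted %s\n",
              length(x$logos), nrow(x$accepted), "k-mers"))
  for (i in seq_along(x$logos)) {
    lg <- x$logos[[i]]
    cat(sprintf("  logo %d: seed %s, %d k-mers, proportion %.3f\n",
                i, lg$seed, nrow(lg$aligned_kmers), lg$proportion))
  }
  invisible(x)
}
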