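# Shared internal helpers: seeded RNG scoping, alphabet conversion, IUPAC
# expansion and small validators used across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of their seed and do
#' not perturb the caller's random stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uppercase and convert DNA-style T to RNA U.
to_rna <- function(x) chartr("Tt", "UU", toupper(as.character(x)))

# Uppercase and convert RNA-style U to DNA T (for genomic sequence matching).
to_dna <- function(x) chartr("Uu", "TT", toupper(as.character(x)))

# IUPAC nucleotide codes expanded to regular-expression character classes.
# Used for degenerate motif matching on character data (e.g. GURAGU-style
# motifs where R = A/G).
.iupac_map <- c(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = "[AG]", Y = "[CU]", S = "[CG]", W = "[AU]",
  K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
  H = "[ACU]", V = "[ACG]", N = "[ACGU]"
)

#' Convert an IUPAC motif to a regular expression over the RNA alphabet
#' @param motif IUPAC nucleotide string (RNA or DNA spelling).
#' @return A regular expression string.
#' @keywords internal
iupac_regex <- function(motif) {
  letters <- strsplit(toupper(as.character(motif)), "")[[1]]
  bad <- setdiff(letters, names(.iupac_map))
  if (length(bad) > 0) {
    stop("invalid IUPAC letters in motif: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste0(.iupac_map[letters], collapse = "")
}

# Assert that x is a single number inside (lo, hi); used by config validation.
check_prob <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- length(x) == 1 && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%g, %g%s, got %s",
                 name, if (open) "(" else "[", lo, hi,
                 if (open) ")" else "]", format(x)),
         call. = FALSE)
  }
  invisible(x)
}

# Detect mixed chromosome-naming dialects ("chr1" vs "1") between two
# interval sets; duplicated dialects silently produce empty overlaps, so we
# warn instead.
warn_mixed_dialects <- function(a, b) {
  ca <- unique(as.character(GenomicRanges::seqnames(a)))
  cb <- unique(as.character(GenomicRanges::seqnames(b)))
  if (length(ca) == 0 || length(cb) == 0) return(invisible(FALSE))
  pa <- any(startsWith(ca, "chr")); pb <- any(startsWith(cb, "chr"))
  if (pa != pb) {
    warning("interval sets use different chromosome naming dialects ",
            "('chr' prefix present in one set only); overlaps may be empty",
            call. = FALSE)
    return(invisible(TRUE))
  }
  invisible(FALSE)
}
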