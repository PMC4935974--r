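# mRNA decay kinetics: RPKM computation, log-linear half-life fits under
# first-order decay N(t) = N(0) exp(-lambda t), a shuffled-time null for the
# goodness-of-fit distribution, and stability classification between
# knockdown and control.

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param counts Gene read counts (>= 0).
#' @param lengths Gene lengths in nt (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM vector: counts x 1e9 / (lengths x total_mapped).
#' @export
rpkm <- function(counts, lengths, total_mapped) {
  if (any(lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (length(total_mapped) != 1 || total_mapped <= 0) {
    stop("total_mapped must be a single count > 0", call. = FALSE)
  }
  counts * 1e9 / (lengths * total_mapped)
}

#' Expression time course container
#'
#' @param rpkm Numeric gene x time matrix of RPKM values (rownames = gene
#'   ids).
#' @param times Hours since transcription shutoff; strictly increasing,
#'   at least 3 points, must include 0.
#' @param condition Label, e.g. `"control"` or `"knockdown"`.
#' @return An `expression_timecourse` object.
#' @export
expression_timecourse <- function(rpkm, times, condition = "control") {
  rpkm <- as.matrix(rpkm)
  if (is.null(rownames(rpkm)) || anyDuplicated(rownames(rpkm))) {
    stop("rpkm matrix needs unique gene ids as rownames", call. = FALSE)
  }
  if (length(times) != ncol(rpkm)) {
    stop("length(times) must match ncol(rpkm)", call. = FALSE)
  }
  if (length(times) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!0 %in% times) stop("time 0 must be present", call. = FALSE)
  if (any(rpkm < 0)) stop("RPKM values must be >= 0", call. = FALSE)
  structure(list(rpkm = rpkm, times = as.numeric(times),
                 condition = condition),
            class = "expression_timecourse")
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat(sprintf("expression_timecourse (%s): %d genes x %d time points (%s h)\n",
              x$condition, nrow(x$rpkm), length(x$times),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Fit first-order decay to one expression series
#'
#' Ordinary least squares of ln(RPKM) on time; the decay rate is minus the
#' slope, the half-life is ln(2)/lambda and the goodness of fit is the
#' coefficient of determination of the log-linear regression. Zero values
#' are replaced by a pseudocount before the log; series with more than
#' `max_zeros` zeros are unusable. A gene is included downstream only if
#' its decay rate is positive and R^2 exceeds `r2_threshold`.
#'
#' @param times Hours (length >= 3).
#' @param values RPKM series.
#' @param pseudocount Replacement for zero RPKM (default 0.01).
#' @param max_zeros Maximum tolerated zero values (default 1).
#' @param r2_threshold Inclusion threshold on R^2 (default 0.6, strict).
#' @return One-row data.frame: `lambda` (per hour), `half_life` (hours, NA
#'   unless lambda > 0), `r_squared`, `usable`, `included`, `reason`.
#' @export
fit_decay <- function(times, values, pseudocount = 0.01, max_zeros = 1,
                      r2_threshold = 0.6) {
  unusable <- function(reason) {
    data.frame(lambda = NA_real_, half_life = NA_real_,
               r_squared = NA_real_, usable = FALSE, included = FALSE,
               reason = reason)
  }
  if (length(times) != length(values)) {
    stop("times and values differ in length", call. = FALSE)
  }
  ok <- is.finite(values)
  if (sum(ok) < 3) return(unusable("fewer than 3 finite values"))
  times <- times[ok]; values <- values[ok]
  nz <- sum(values == 0)
  if (nz > max_zeros) return(unusable("more than max_zeros zero values"))
  values[values == 0] <- pseudocount
  y <- log(values)
  if (stats::sd(y) == 0) {
    # flat series: zero decay rate, no explainable variance
    lambda <- 0; r2 <- 0
  } else {
    fit <- stats::lm(y ~ times)
    lambda <- -unname(stats::coef(fit)[2])
    r2 <- stats::cor(times, y)^2
  }
  data.frame(
    lambda = lambda,
    half_life = if (lambda > 0) log(2) / lambda else NA_real_,
    r_squared = r2,
    usable = TRUE,
    included = lambda > 0 && r2 > r2_threshold,
    reason = ""
  )
}

#' Fit decay to every gene of a time course
#'
#' Applies [fit_decay()] per gene after an expression floor: genes with
#' RPKM <= `min_expression` at time 0 are excluded as not expressed.
#'
#' @param tc An `expression_timecourse`.
#' @param min_expression Expression floor on the t = 0 RPKM (default 1).
#' @inheritParams fit_decay
#' @return Data.frame with one row per gene: `gene` plus the [fit_decay()]
#'   columns.
#' @export
fit_decay_all <- function(tc, pseudocount = 0.01, max_zeros = 1,
                          r2_threshold = 0.6, min_expression = 1) {
  stopifnot(inherits(tc, "expression_timecourse"))
  t0 <- which(tc$times == 0)
  rows <- lapply(rownames(tc$rpkm), function(g) {
    v <- tc$rpkm[g, ]
    if (v[t0] <= min_expression) {
      return(data.frame(lambda = NA_real_, half_life = NA_real_,
                        r_squared = NA_real_, usable = FALSE,
                        included = FALSE, reason = "not expressed at t0"))
    }
    fit_decay(tc$times, v, pseudocount = pseudocount, max_zeros = max_zeros,
              r2_threshold = r2_threshold)
  })
  out <- do.call(rbind, rows)
  out <- cbind(gene = rownames(tc$rpkm), out)
  rownames(out) <- NULL
  out
}

#' Shuffled-time null for decay goodness of fit
#'
#' Permutes, within each gene, the expression values across time points
#' (simple uniform permutation, identity allowed), refits the decay model,
#' and compares the real and shuffled R^2 distributions with a two-sample
#' two-sided Kolmogorov-Smirnov test. Only genes with a usable real fit
#' enter both distributions.
#'
#' @param tc An `expression_timecourse`.
#' @param seed Integer seed for the permutations.
#' @inheritParams fit_decay_all
#' @return List: `r2_real`, `r2_shuffled`, `median_real`,
#'   `median_shuffled`, `ks_statistic`, `ks_p`.
#' @export
shuffled_null <- function(tc, seed, pseudocount = 0.01, max_zeros = 1,
                          r2_threshold = 0.6, min_expression = 1) {
  real <- fit_decay_all(tc, pseudocount, max_zeros, r2_threshold,
                        min_expression)
  usable <- real$usable
  r2_real <- real$r_squared[usable]
  if (length(r2_real) == 0) stop("no usable fits", call. = FALSE)
  genes <- real$gene[usable]
  r2_shuffled <- with_seed(seed, {
    vapply(genes, function(g) {
      v <- sample(tc$rpkm[g, ])
      fit_decay(tc$times, v, pseudocount = pseudocount,
                max_zeros = max_zeros,
                r2_threshold = r2_threshold)$r_squared
    }, 0)
  })
  ks <- suppressWarnings(stats::ks.test(r2_real, r2_shuffled,
                                        alternative = "two.sided"))
  list(r2_real = unname(r2_real), r2_shuffled = unname(r2_shuffled),
       median_real = stats::median(r2_real),
       median_shuffled = stats::median(r2_shuffled),
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}

#' Classify half-life changes between knockdown and control
#'
#' Genes included in both conditions (positive decay rate, R^2 above the
#' fit threshold) are classified by log2(t1/2 knockdown / t1/2 control):
#' above `threshold` stabilized, below -`threshold` destabilized, otherwise
#' unchanged. Genes failing inclusion in either condition are reported as
#' unevaluable.
#'
#' @param fits_kd,fits_ctrl Data.frames from [fit_decay_all()].
#' @param threshold Absolute log2 half-life change required (default 1).
#' @return Data.frame: `gene`, `half_life_ctrl`, `half_life_kd`,
#'   `log2_hl_change`, `evaluable`, `call` (factor stabilized /
#'   destabilized / unchanged, NA when unevaluable).
#' @export
classify_stability <- function(fits_kd, fits_ctrl, threshold = 1) {
  m <- merge(fits_ctrl[, c("gene", "half_life", "included")],
             fits_kd[, c("gene", "half_life", "included")],
             by = "gene", suffixes = c("_ctrl", "_kd"))
  evaluable <- m$included_ctrl & m$included_kd
  change <- ifelse(evaluable, log2(m$half_life_kd / m$half_life_ctrl),
                   NA_real_)
  call <- rep(NA_character_, nrow(m))
  call[evaluable & change > threshold] <- "stabilized"
  call[evaluable & change < -threshold] <- "destabilized"
  call[evaluable & abs(change) <= threshold] <- "unchanged"
  data.frame(
    gene = m$gene,
    half_life_ctrl = m$half_life_ctrl,
    half_life_kd = m$half_life_kd,
    log2_hl_change = change,
    evaluable = evaluable,
    call = factor(call, levels = c("stabilized", "destabilized", "unchanged"))
  )
}
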