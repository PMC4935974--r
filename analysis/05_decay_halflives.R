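#!/usr/bin/env Rscript

# Stage 5: mRNA half-lives from the transcription-shutoff courses.
#
# Log-linear fits of ln(RPKM) on time per gene (lambda = -slope,
# t1/2 = ln2/lambda; keep lambda > 0 and R^2 > 0.6), a shuffled-time null
# on the R^2 distribution, and stability classification of knockdown vs
# control at |log2 half-life change| > 1.

library(rbpkit)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
decay <- simulate_decay(cfg)

fits_ctrl <- fit_decay_all(decay$control)
fits_kd <- fit_decay_all(decay$knockdown)
write_tsv(fits_ctrl, file.path(out, "decay_fits_control.tsv"))
write_tsv(fits_kd, file.path(out, "decay_fits_knockdown.tsv"))
message(sprintf("control: %d/%d genes pass lambda > 0 and R^2 > 0.6",
                sum(fits_ctrl$included), nrow(fits_ctrl)))

m <- merge(fits_ctrl[fits_ctrl$included, ], decay$truth, by = "gene")
rel_err <- abs(m$half_life - m$half_life_ctrl) / m$half_life_ctrl
message(sprintf("median relative half-life error: %.1f%%",
                100 * stats::median(rel_err)))

nl <- shuffled_null(decay$control, seed = seed + 1)
write_tsv(data.frame(r2_real = nl$r2_real, r2_shuffled = nl$r2_shuffled),
          file.path(out, "decay_r2_real_vs_shuffled.tsv"))
message(sprintf(
  "median R^2: %.2f (real) vs %.2f (shuffled); KS D = %.2f, P = %.3g",
  nl$median_real, nl$median_shuffled, nl$ks_statistic, nl$ks_p))

calls <- classify_stability(fits_kd, fits_ctrl)
write_tsv(calls, file.path(out, "stability_calls.tsv"))
tab <- table(calls$call)
message(sprintf("stability calls: %d stabilized, %d destabilized, %d unchanged (%d unevaluable)",
                tab[["stabilized"]], tab[["destabilized"]],
                tab[["unchanged"]], sum(!calls$evaluable)))
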