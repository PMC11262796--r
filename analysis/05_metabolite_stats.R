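#!/usr/bin/env Rscript
# Stage 5: metabolomic index statistics. Intra-sample TCA ratios
# (succinate/fumarate, citrate/succinate, fumarate/malate) with Student
# t-tests and BH correction across the panel, adenylate energy-state indices
# (energy charge, AMP fraction, ATP/ADP), and per-metabolite fold changes.

suppressPackageStartupMessages(library(fluxcontrast))

inp <- "results/analysis/01_inputs"
out <- "results/analysis/05_metabolite_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

df <- read.delim(file.path(inp, "metabolomics.tsv"))
ab <- as.matrix(df[, -1]); rownames(ab) <- df[[1]]
tab <- metabolite_table(ab, sub("_.*$", "", colnames(ab)))

pairs <- list(c("succinate", "fumarate"), c("citrate", "succinate"),
              c("fumarate", "malate"))
rows <- lapply(pairs, function(pr) {
  rs <- intra_sample_ratio(tab, pr[1], pr[2])
  data.frame(numerator = pr[1], denominator = pr[2],
             mean_A = rs$mean[["A"]], sd_A = rs$sd[["A"]],
             mean_B = rs$mean[["B"]], sd_B = rs$sd[["B"]],
             t = rs$t, p = rs$p)
})
ratios <- do.call(rbind, rows)
ratios$q <- bh_adjust(ratios$p)
write.table(ratios, file.path(out, "tca_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(ratios))) {
  message(sprintf("%s/%s: A %.2f+/-%.2f vs B %.2f+/-%.2f (q = %.3g)",
                  ratios$numerator[i], ratios$denominator[i],
                  ratios$mean_A[i], ratios$sd_A[i],
                  ratios$mean_B[i], ratios$sd_B[i], ratios$q[i]))
}

energy <- adenylate_indices(tab)
write.table(energy$summary, file.path(out, "adenylate_indices.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
es <- energy$summary
for (i in seq_len(nrow(es))) {
  message(sprintf("%s: A %.3f vs B %.3f (q = %.3g)", es$index[i],
                  es$mean_A[i], es$mean_B[i], es$q[i]))
}

fc <- fold_changes(tab, numerator_group = "A")
write.table(fc, file.path(out, "fold_changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("metabolite statistics written to ", out)
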