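#!/usr/bin/env Rscript
# Adjacent-day (and endpoint) differential abundance on log2 intensities:
# empirical-Bayes moderated t-tests with BH correction, volcano tables
# under both the significance (0.05) and display (1e-4) cutoffs.

suppressMessages(library(stemtrace))
io <- read_matrix("results/preprocess/normalized_matrix.tsv",
                  "results/data/timecourse_meta.tsv")
io$matrix <- replace_missing_with_zero(io$matrix)
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

logm <- log_transform(io$matrix)
days <- sort(unique(io$meta$day))
pairs <- rbind(cbind(days[-length(days)], days[-1]),
               c(days[1], days[length(days)]))
for (i in seq_len(nrow(pairs))) {
  g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
  res <- moderated_t_test(logm, io$meta, g1, g2)
  pr <- attr(res, "prior")
  res <- res[order(res$p_adjusted, res$p), ]
  write.table(res, file.path(out, sprintf("diff_d%g_vs_d%g.tsv", g1, g2)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  vt <- volcano_table(res, p_cutoff = 0.05, lfc_cutoff = 1)
  write.table(vt, file.path(out, sprintf("volcano_d%g_vs_d%g.tsv", g1, g2)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("d%g vs d%g: prior d0 = %.2f, s0^2 = %.3f; %d significant (adj p < 0.05 & |logFC| > 1)\n",
              g1, g2, pr$d0, pr$s02, sum(res$significant)))
}
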