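#!/usr/bin/env Rscript
# Generate the synthetic study datasets with planted ground truth:
#   (a) a differentiation time course (days 0/3/5/7/10 x 3 replicates,
#       2000 proteins, 50 day-specific markers per day at +2 log2), and
#   (b) paired two-condition (NM/OM) endpoint and primary-reference
#       matrices with one dominant discordant protein (vimentin analog).
# Writes TSVs under results/data/.

suppressMessages(library(stemtrace))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

sim <- simulate_timecourse(sim_config(seed = seed))
write_matrix(sim$matrix, file.path(out, "timecourse_matrix.tsv"), sim$meta,
             file.path(out, "timecourse_meta.tsv"))
truth <- data.frame(protein = names(sim$truth$archetype),
                    archetype = sim$truth$archetype,
                    marker_day = sim$truth$marker_day[names(sim$truth$archetype)])
write.table(truth, file.path(out, "timecourse_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
cat(sprintf("time course: %d proteins x %d samples, %d planted markers, %.1f%% missing\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            length(sim$truth$marker_day), 100 * mean(sim$matrix$missing)))

pair <- simulate_condition_matrices(seed = seed)
write_matrix(pair$derived$matrix, file.path(out, "derived_matrix.tsv"),
             pair$derived$meta, file.path(out, "derived_meta.tsv"))
write_matrix(pair$reference$matrix, file.path(out, "reference_matrix.tsv"),
             pair$reference$meta, file.path(out, "reference_meta.tsv"))
cat(sprintf("condition pair: outlier (vimentin analog) = %s; target r: NM %.2f, OM %.2f\n",
            pair$truth$outlier_protein, pair$truth$target_r[["NM"]],
            pair$truth$target_r[["OM"]]))
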