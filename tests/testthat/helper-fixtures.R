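# Small in-code fixtures shared across test files.

# A named abundance matrix from a plain numeric matrix.
tiny_matrix <- function(values, unique_peptides = NULL, missing = NULL,
                        proteins = sprintf("P%02d", seq_len(nrow(values))),
                        samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(proteins, samples)
  if (!is.null(missing)) dimnames(missing) <- dimnames(values)
  abundance_matrix(values, unique_peptides = unique_peptides,
                   missing = missing)
}

# Metadata for a days x replicates layout matching simulate_timecourse ids.
tiny_meta <- function(days, n_replicates, condition = "differentiation") {
  data.frame(
    sample_id = sprintf("d%g_r%d", rep(days, each = n_replicates),
                        rep(seq_len(n_replicates), length(days))),
    day = rep(days, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(days)),
    condition = condition, stringsAsFactors = FALSE)
}

# Matrix laid out to match tiny_meta column order.
tiny_timecourse <- function(values, days, n_replicates) {
  meta <- tiny_meta(days, n_replicates)
  m <- tiny_matrix(values, samples = meta$sample_id)
  list(matrix = m, meta = meta)
}
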