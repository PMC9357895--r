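#' Protein abundance matrix with missingness mask
#'
#' Container for a label-free quantitation (LFQ) style protein intensity
#' table: a proteins x samples matrix of non-negative intensities, a logical
#' mask marking entries that were missing in the source data, and per-protein
#' unique-peptide counts used for master-protein filtering.
#'
#' Missing entries are carried as \code{NA} in \code{values} until
#' \code{\link{replace_missing_with_zero}} sets them to 0; the mask is kept
#' either way so downstream stages can distinguish structural zeros from
#' measured zeros.
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   unique dimnames. Non-missing entries must be finite and >= 0.
#' @param unique_peptides integer vector of unique-peptide counts, one per
#'   protein (recycled names from \code{rownames(values)} if unnamed).
#'   Defaults to \code{NA} counts (filtering then requires them explicitly).
#' @param missing logical matrix of the same shape; defaults to
#'   \code{is.na(values)}.
#' @return an object of class \code{abundance_matrix}: a list with elements
#'   \code{values}, \code{missing}, \code{unique_peptides}.
#' @export
abundance_matrix <- function(values, unique_peptides = NULL, missing = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (is.null(missing)) missing <- is.na(values)
  if (!is.logical(missing) || !identical(dim(missing), dim(values)))
    stop("'missing' must be a logical matrix of the same shape as 'values'")
  obs <- values[!missing]
  if (any(!is.finite(obs)))
    stop("non-finite intensity in non-missing entries")
  if (any(obs < 0))
    stop("negative intensity values are not allowed")
  if (is.null(unique_peptides)) {
    unique_peptides <- rep(NA_integer_, nrow(values))
  }
  if (length(unique_peptides) != nrow(values))
    stop("'unique_peptides' must have one entry per protein")
  if (any(!is.na(unique_peptides) & unique_peptides < 0))
    stop("'unique_peptides' must be >= 0")
  unique_peptides <- stats::setNames(as.integer(round(unique_peptides)),
                                     rownames(values))
  structure(
    list(values = values, missing = missing,
         unique_peptides = unique_peptides),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

protein_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

# Tokens accepted as missing on read (documented dialect).
.missing_tokens <- c("", "NA", "NaN")

#' Read an abundance matrix and its sample metadata from TSV
#'
#' The matrix file has one row per protein: a \code{protein_id} column, an
#' optional \code{unique_peptides} column, and one column per sample; empty
#' cells, \code{NA} and \code{NaN} are read as missing. The metadata file has
#' columns \code{sample_id}, \code{day}, \code{replicate}, \code{condition}.
#'
#' @param matrix_path path to the abundance TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return list with elements \code{matrix} (an
#'   \code{\link{abundance_matrix}}) and \code{meta} (a data frame ordered to
#'   match the matrix samples).
#' @export
read_matrix <- function(matrix_path, meta_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           na.strings = .missing_tokens,
                           stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(tab))
    stop("matrix file must have a 'protein_id' column")
  up <- NULL
  if ("unique_peptides" %in% names(tab)) {
    up <- tab$unique_peptides
    tab$unique_peptides <- NULL
  }
  ids <- as.character(tab$protein_id)
  tab$protein_id <- NULL
  values <- as.matrix(tab)
  if (!is.numeric(values)) stop("non-numeric entries in abundance matrix")
  rownames(values) <- ids
  m <- abundance_matrix(values, unique_peptides = up)

  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- validate_meta(m, meta)
  list(matrix = m, meta = meta)
}

#' Validate sample metadata against an abundance matrix
#'
#' Checks that every sample has exactly one metadata row and reorders the
#' metadata to the matrix column order.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @param meta data frame with columns \code{sample_id}, \code{day},
#'   \code{replicate}, \code{condition}.
#' @return the metadata, ordered to match \code{sample_ids(m)}.
#' @export
validate_meta <- function(m, meta) {
  need <- c("sample_id", "day", "replicate", "condition")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  orphan <- setdiff(sample_ids(m), meta$sample_id)
  if (length(orphan))
    stop("samples missing from metadata: ", paste(orphan, collapse = ", "))
  meta <- meta[match(sample_ids(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Write an abundance matrix (and optionally metadata) to TSV
#'
#' Missing entries are written as empty cells, the dialect accepted by
#' \code{\link{read_matrix}}.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @param matrix_path output path for the abundance TSV.
#' @param meta optional sample metadata data frame.
#' @param meta_path output path for the metadata TSV (required when
#'   \code{meta} is given).
#' @return invisibly, the matrix path.
#' @export
write_matrix <- function(m, matrix_path, meta = NULL, meta_path = NULL) {
  vals <- m$values
  vals[m$missing] <- NA
  out <- data.frame(protein_id = rownames(vals),
                    unique_peptides = m$unique_peptides,
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(out, matrix_path)
  if (!is.null(meta)) {
    if (is.null(meta_path)) stop("'meta_path' required when writing metadata")
    write_tsv(meta, meta_path)
  }
  invisible(matrix_path)
}

# Uniform TSV writer: tab-separated, no quoting, NA as empty cell.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
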