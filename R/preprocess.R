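#' Keep master proteins supported by enough unique peptides
#'
#' Quantification is restricted to master proteins supported by more than
#' two unique peptides; the default \code{min_unique_peptides = 3} encodes
#' that "strictly more than 2" convention and is configurable.
#'
#' @param m an \code{\link{abundance_matrix}} with populated
#'   \code{unique_peptides}.
#' @param min_unique_peptides smallest unique-peptide count retained
#'   (proteins with \code{unique_peptides >= min_unique_peptides} are kept).
#' @return the filtered \code{abundance_matrix}; an empty result is allowed
#'   and reported via a message.
#' @export
filter_master_proteins <- function(m, min_unique_peptides = 3) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (min_unique_peptides > 0 && anyNA(m$unique_peptides))
    stop("unique_peptides must be populated to filter master proteins")
  keep <- if (min_unique_peptides <= 0) rep(TRUE, nrow(m$values))
          else m$unique_peptides >= min_unique_peptides
  if (!any(keep)) message("filter_master_proteins: no proteins retained")
  abundance_matrix(m$values[keep, , drop = FALSE],
                   unique_peptides = m$unique_peptides[keep],
                   missing = m$missing[keep, , drop = FALSE])
}

#' Replace missing intensities with zero
#'
#' Missing values are treated as below the detection limit and set to zero;
#' the missingness mask is preserved so later stages can distinguish these
#' structural zeros from measured values.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @return the matrix with every masked entry set to 0.
#' @export
replace_missing_with_zero <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  m$values[m$missing] <- 0
  m
}

#' Per-sample median normalization
#'
#' Each sample is divided by the median of its nonzero (and non-missing)
#' entries, so that after normalization every sample's nonzero median equals
#' one. Zeros are excluded from the median because after missing-to-zero
#' replacement a raw median would be distorted by censoring depth.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @return list with elements \code{matrix} (normalized) and \code{factors}
#'   (the per-sample divisors applied).
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  factors <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    x <- x[!m$missing[, j] & !is.na(x) & x > 0]
    if (!length(x))
      stop("sample has no nonzero entries: ", colnames(vals)[j])
    stats::median(x)
  }, numeric(1))
  names(factors) <- colnames(vals)
  m$values <- sweep(vals, 2, factors, "/")
  list(matrix = m, factors = factors)
}

#' Standard preprocessing pipeline
#'
#' Applies, in order: master-protein filtering, missing-to-zero replacement,
#' and per-sample median normalization, and records the steps taken.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @param meta sample metadata (validated and reordered against \code{m}).
#' @param min_unique_peptides passed to \code{\link{filter_master_proteins}};
#'   use 0 to skip filtering.
#' @param normalize logical; apply \code{\link{median_normalize}}.
#' @return list with \code{matrix}, \code{meta}, \code{factors} (NULL when
#'   not normalized) and \code{log}, a character record of the steps run.
#' @export
preprocess <- function(m, meta, min_unique_peptides = 3, normalize = TRUE) {
  meta <- validate_meta(m, meta)
  log <- character(0)
  n0 <- nrow(m$values)
  m <- filter_master_proteins(m, min_unique_peptides)
  log <- c(log, sprintf("filter_master_proteins(min=%d): %d -> %d proteins",
                        min_unique_peptides, n0, nrow(m$values)))
  n_missing <- sum(m$missing)
  m <- replace_missing_with_zero(m)
  log <- c(log, sprintf("replace_missing_with_zero: %d entries", n_missing))
  factors <- NULL
  if (normalize) {
    nn <- median_normalize(m)
    m <- nn$matrix
    factors <- nn$factors
    log <- c(log, "median_normalize: per-sample nonzero median set to 1")
  }
  list(matrix = m, meta = meta, factors = factors, log = log)
}
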