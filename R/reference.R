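#' Per-protein mean abundance over selected samples
#'
#' Arithmetic mean of each protein's normalized abundance over the samples
#' matching the given condition and/or day.
#'
#' @param m an \code{\link{abundance_matrix}}.
#' @param meta sample metadata.
#' @param condition optional condition label filter.
#' @param day optional day label filter.
#' @return named numeric vector of per-protein means.
#' @export
mean_abundance_vector <- function(m, meta, condition = NULL, day = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  meta <- validate_meta(m, meta)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(condition)) keep <- keep & meta$condition %in% condition
  if (!is.null(day)) keep <- keep & meta$day %in% day
  if (!any(keep))
    stop(sprintf("no samples match selector (condition = %s, day = %s)",
                 if (is.null(condition)) "*" else paste(condition, collapse = "/"),
                 if (is.null(day)) "*" else paste(day, collapse = "/")))
  vals <- m$values
  if (anyNA(vals))
    stop("matrix has unreplaced missing values; run replace_missing_with_zero() first")
  rowMeans(vals[, meta$sample_id[keep], drop = FALSE])
}

#' Pearson correlation with preconditions
#'
#' Standard product-moment correlation of two equal-length vectors,
#' erroring on degenerate input (length < 3 or zero variance) instead of
#' returning \code{NA}.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Leave-one-protein-out influence on a Pearson correlation
#'
#' Computes the full correlation of two mean-abundance vectors and, for
#' each protein, the correlation with that protein excluded (by direct
#' recomputation). The protein with the largest absolute change is the top
#' influencer, reported with the correlation excluding it -- the
#' with/without presentation used when a single dominant protein (such as
#' vimentin) distorts a derived-vs-reference comparison.
#'
#' @param x,y paired numeric vectors (length >= 4), typically from
#'   \code{\link{mean_abundance_vector}}.
#' @param ids protein ids (default \code{names(x)}).
#' @param condition optional condition label carried into the report.
#' @return object of class \code{correlation_report}: list with
#'   \code{r_full}, \code{influence} (data frame: \code{protein},
#'   \code{r_without}, \code{delta_r}), \code{top_influencer},
#'   \code{r_without_top}, \code{n}, \code{condition}. Proteins whose
#'   removal leaves a zero-variance vector get \code{NA} influence and are
#'   excluded from the top-influencer argmax; ties break to the
#'   lexicographically smallest id.
#' @export
influence_leave_one_out <- function(x, y, ids = names(x), condition = NA) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 4) stop("need >= 4 paired observations")
  if (is.null(ids)) ids <- as.character(seq_along(x))
  if (length(ids) != length(x)) stop("'ids' must match the vector length")
  r_full <- pearson_r(x, y)
  # direct recomputation per protein; zero-variance removals surface as NA
  r_without <- suppressWarnings(
    vapply(seq_along(x), function(i) stats::cor(x[-i], y[-i]), numeric(1)))
  delta <- r_without - r_full
  influence <- data.frame(protein = ids, r_without = r_without,
                          delta_r = delta, stringsAsFactors = FALSE)
  ok <- which(!is.na(delta))
  top_i <- ok[order(-abs(delta[ok]), ids[ok])][1]
  structure(list(r_full = r_full, influence = influence,
                 top_influencer = ids[top_i],
                 r_without_top = r_without[top_i],
                 n = length(x), condition = condition),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "correlation_report%s: n = %d, r = %.3f; top influencer %s (r without it = %.3f)\n",
    if (is.na(x$condition)) "" else sprintf(" [%s]", x$condition),
    x$n, x$r_full, x$top_influencer, x$r_without_top))
  invisible(x)
}

#' Compare a derived proteome to a reference per condition and timepoint
#'
#' For each (condition, timepoint) pair, correlates the derived dataset's
#' mean protein abundances against the reference's mean abundances for the
#' same condition, over the proteins detected (nonzero mean) in both
#' datasets, and runs the leave-one-out influence analysis. Reports the
#' correlation with and without the top influencer, mirroring the
#' with/without-vimentin presentation.
#'
#' @param derived,reference lists with elements \code{matrix} (an
#'   \code{\link{abundance_matrix}}) and \code{meta}.
#' @param conditions condition labels to compare (default: those shared by
#'   both metadata tables).
#' @param timepoints derived day labels (default: all days in the derived
#'   metadata).
#' @param log2 correlate \code{log2(mean + pseudocount)} instead of the
#'   normalized raw scale (default \code{FALSE}; use \code{TRUE} when the
#'   quantity of interest lives on the log scale).
#' @param pseudocount offset used when \code{log2 = TRUE}.
#' @param exclude protein ids to drop from every comparison before the
#'   analysis (a named exclusion like the vimentin removal).
#' @return list with \code{reports} (data frame: \code{condition},
#'   \code{timepoint}, \code{n_shared}, \code{r_full},
#'   \code{top_influencer}, \code{delta_r}, \code{r_without_top}) and
#'   \code{details}, the per-pair \code{correlation_report} objects.
#' @export
compare_conditions <- function(derived, reference, conditions = NULL,
                               timepoints = NULL, log2 = FALSE,
                               pseudocount = 1, exclude = character(0)) {
  dm <- derived$matrix; dmeta <- validate_meta(dm, derived$meta)
  rm_ <- reference$matrix; rmeta <- validate_meta(rm_, reference$meta)
  if (is.null(conditions))
    conditions <- intersect(unique(dmeta$condition), unique(rmeta$condition))
  if (!length(conditions)) stop("no shared condition labels")
  if (is.null(timepoints)) timepoints <- sort(unique(dmeta$day))
  details <- list()
  rows <- list()
  for (cc in conditions) {
    ref_vec <- mean_abundance_vector(rm_, rmeta, condition = cc)
    for (tp in timepoints) {
      der_vec <- mean_abundance_vector(dm, dmeta, condition = cc, day = tp)
      shared <- intersect(names(der_vec)[der_vec > 0],
                          names(ref_vec)[ref_vec > 0])
      shared <- setdiff(shared, exclude)
      if (length(shared) < 3)
        stop(sprintf("fewer than 3 shared detected proteins for (%s, day %s)",
                     cc, format(tp)))
      xv <- der_vec[shared]; yv <- ref_vec[shared]
      if (log2) {
        xv <- log2(xv + pseudocount)
        yv <- log2(yv + pseudocount)
      }
      rep_ <- influence_leave_one_out(xv, yv, ids = shared, condition = cc)
      key <- sprintf("%s_d%s", cc, format(tp))
      details[[key]] <- rep_
      rows[[key]] <- data.frame(
        condition = cc, timepoint = tp, n_shared = rep_$n,
        r_full = rep_$r_full, top_influencer = rep_$top_influencer,
        delta_r = rep_$r_without_top - rep_$r_full,
        r_without_top = rep_$r_without_top, stringsAsFactors = FALSE)
    }
  }
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL
  list(reports = reports, details = details)
}
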