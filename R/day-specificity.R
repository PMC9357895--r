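#' Day-specificity z-score of protein abundance
#'
#' For every protein j and day d, compares the mean normalized abundance of
#' the protein over the samples of that day against the protein's mean and
#' standard deviation over all samples:
#' \deqn{Z_{jd} = (\langle p \rangle_{jd} - \langle p \rangle_j^{all}) / \sigma_j}
#' with \eqn{\sigma_j} the sample (n-1) standard deviation over all samples.
#' The centring and scaling are per protein: a pooled cross-protein scale
#' would be dominated by the abundance dynamic range and could not support a
#' single specificity cutoff. Proteins with \eqn{\sigma_j = 0} (constant or
#' all-zero) get \eqn{Z = 0} for every day.
#'
#' @param m an \code{\link{abundance_matrix}} of preprocessed (normalized)
#'   abundances.
#' @param meta sample metadata; its \code{day} column defines the groups
#'   (>= 2 distinct days, each with >= 1 sample).
#' @param log2 compute on \code{log2(x + 1)} abundances instead of the
#'   normalized scale (default \code{FALSE}, matching the pipeline order in
#'   which the statistic follows normalization directly).
#' @return object of class \code{day_specificity}: list with \code{zscores}
#'   (proteins x days), \code{day_means}, \code{overall_mean},
#'   \code{overall_sd}, \code{days}, \code{n_per_day}.
#' @export
zscore_abundance <- function(m, meta, log2 = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  meta <- validate_meta(m, meta)
  days <- sort(unique(meta$day))
  if (length(days) < 2) stop("need >= 2 day groups")
  vals <- m$values
  if (anyNA(vals))
    stop("matrix has unreplaced missing values; run replace_missing_with_zero() first")
  if (log2) vals <- log2(vals + 1)
  n_per_day <- stats::setNames(
    vapply(days, function(d) sum(meta$day == d), integer(1)),
    as.character(days))
  if (any(n_per_day == 0)) stop("empty day group")
  overall_mean <- rowMeans(vals)
  overall_sd <- apply(vals, 1, stats::sd)
  day_means <- matrix(
    vapply(days, function(d)
      rowMeans(vals[, meta$day == d, drop = FALSE]), numeric(nrow(vals))),
    nrow = nrow(vals),
    dimnames = list(rownames(vals), as.character(days)))
  z <- (day_means - overall_mean) / overall_sd
  z[overall_sd == 0, ] <- 0
  structure(list(zscores = z, day_means = day_means,
                 overall_mean = overall_mean, overall_sd = overall_sd,
                 days = days, n_per_day = n_per_day),
            class = "day_specificity")
}

#' @export
print.day_specificity <- function(x, ...) {
  cat(sprintf("day_specificity: %d proteins x %d days (%s)\n",
              nrow(x$zscores), length(x$days),
              paste(x$days, collapse = ", ")))
  invisible(x)
}

#' Per-day sets of day-specific proteins
#'
#' A protein is specific to day d when its day-specificity z-score exceeds
#' the threshold (strict inequality). A protein can be specific to several
#' days; the number of such days is its multiplicity.
#'
#' @param z a \code{\link{zscore_abundance}} result.
#' @param threshold positive specificity cutoff (default 1.5).
#' @return list with \code{sets} (per-day character vectors of protein ids),
#'   \code{multiplicity} (named integer per protein) and \code{threshold}.
#' @export
day_specific_sets <- function(z, threshold = 1.5) {
  stopifnot(inherits(z, "day_specificity"))
  hits <- z$zscores > threshold
  sets <- lapply(colnames(hits), function(d) rownames(hits)[hits[, d]])
  names(sets) <- colnames(hits)
  list(sets = sets,
       multiplicity = stats::setNames(as.integer(rowSums(hits)),
                                      rownames(hits)),
       threshold = threshold)
}

#' Threshold scan balancing specific-protein count against multiplicity
#'
#' For each candidate threshold, counts the proteins specific to at least
#' one day and the mean multiplicity among them. The selected threshold is
#' the smallest grid value whose mean multiplicity is at most
#' \code{1 + tol}: small enough to keep as many proteins as possible, large
#' enough that a specific protein typically points at a single day. If no
#' grid value attains the criterion the largest one is returned with a
#' warning.
#'
#' @param z a \code{\link{zscore_abundance}} result.
#' @param grid increasing candidate thresholds.
#' @param tol multiplicity slack above 1 (default 0.05).
#' @return object of class \code{threshold_scan}: a data frame with columns
#'   \code{threshold}, \code{n_specific}, \code{mean_multiplicity}, plus
#'   attributes \code{selected} and \code{tol}.
#' @export
scan_threshold <- function(z, grid = seq(0.5, 3, by = 0.1), tol = 0.05) {
  stopifnot(inherits(z, "day_specificity"))
  if (!length(grid) || any(diff(grid) <= 0))
    stop("'grid' must be non-empty and increasing")
  rows <- lapply(grid, function(th) {
    s <- day_specific_sets(z, th)
    mult <- s$multiplicity[s$multiplicity > 0]
    data.frame(threshold = th, n_specific = length(mult),
               mean_multiplicity = if (length(mult)) mean(mult) else NA_real_)
  })
  scan <- do.call(rbind, rows)
  ok <- !is.na(scan$mean_multiplicity) & scan$mean_multiplicity <= 1 + tol
  if (any(ok)) {
    selected <- scan$threshold[which(ok)[1]]
  } else {
    warning("no threshold reaches mean multiplicity <= 1 + tol; returning the largest")
    selected <- max(grid)
  }
  structure(scan, class = c("threshold_scan", "data.frame"),
            selected = selected, tol = tol)
}

#' Hypergeometric over-representation of annotation terms
#'
#' One-sided (upper tail) hypergeometric test of each annotation term
#' against a protein set drawn from a background universe, with
#' Benjamini-Hochberg adjustment across the tested terms. Terms are first
#' intersected with the background; terms smaller than \code{min_term_size}
#' after intersection are skipped.
#'
#' @param set character vector of protein ids (must be a subset of
#'   \code{background}).
#' @param annotations named list of character vectors: term -> member ids
#'   (GMT-style sets, see \code{\link{read_gmt}}).
#' @param background character vector: the tested universe.
#' @param min_term_size smallest in-background term size tested.
#' @return data frame with one row per tested term: \code{term},
#'   \code{overlap}, \code{set_size}, \code{term_size},
#'   \code{background_size}, \code{p}, \code{p_adjusted}; ordered by
#'   \code{p}.
#' @export
enrich <- function(set, annotations, background, min_term_size = 2) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  set <- unique(set)
  if (!all(set %in% background))
    stop("'set' must be a subset of 'background'")
  terms <- lapply(annotations, function(g) intersect(unique(g), background))
  keep <- vapply(terms, length, integer(1)) >= min_term_size
  terms <- terms[keep]
  if (!length(terms))
    return(data.frame(term = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      p_adjusted = numeric(0)))
  N <- length(background)
  n <- length(set)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(set, terms[[tm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, set_size = n, term_size = K,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_hochberg(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read annotation sets in GMT format
#'
#' One term per line: term name, description, then tab-separated member
#' ids.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}
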