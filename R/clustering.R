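#' Build combined-replicate temporal abundance profiles
#'
#' Converts a normalized time-course matrix into one profile row per
#' (protein, replicate) pair: the protein's abundance per day in that
#' replicate (averaged when a (day, replicate) cell holds several samples),
#' normalized to unit sum over days (\code{norm = "sum"}, the
#' fraction-of-total convention) or to unit maximum (\code{norm = "max"}).
#' Replicates are pooled into a single row set so that clustering treats
#' them as exchangeable observations of the same temporal program.
#'
#' Rows whose raw profile is all zero carry no shape information and are
#' dropped; the count is reported via a message and kept in the result.
#'
#' @param m an \code{\link{abundance_matrix}} (preprocessed).
#' @param meta sample metadata; every (day, replicate) combination must have
#'   at least one sample.
#' @param norm profile normalization, \code{"sum"} or \code{"max"}.
#' @return object of class \code{profile_set}: list with \code{profiles}
#'   (rows = protein x replicate, columns = days), \code{protein},
#'   \code{replicate}, \code{days}, \code{n_dropped}.
#' @export
build_profiles <- function(m, meta, norm = c("sum", "max")) {
  stopifnot(inherits(m, "abundance_matrix"))
  norm <- match.arg(norm)
  meta <- validate_meta(m, meta)
  days <- sort(unique(meta$day))
  reps <- sort(unique(meta$replicate))
  vals <- m$values
  if (anyNA(vals))
    stop("matrix has unreplaced missing values; run replace_missing_with_zero() first")
  cells <- expand.grid(day = days, replicate = reps)
  have <- mapply(function(d, r) any(meta$day == d & meta$replicate == r),
                 cells$day, cells$replicate)
  if (!all(have))
    stop("missing (day, replicate) combination: ",
         paste(sprintf("(d%g, r%s)", cells$day[!have], cells$replicate[!have]),
               collapse = ", "))
  blocks <- lapply(reps, function(r) {
    prof <- vapply(days, function(d) {
      idx <- meta$day == d & meta$replicate == r
      rowMeans(vals[, idx, drop = FALSE])
    }, numeric(nrow(vals)))
    colnames(prof) <- as.character(days)
    rownames(prof) <- sprintf("%s.r%s", rownames(vals), r)
    prof
  })
  profiles <- do.call(rbind, blocks)
  protein <- rep(rownames(vals), times = length(reps))
  replicate <- rep(reps, each = nrow(vals))
  total <- rowSums(profiles)
  drop <- total == 0
  if (any(drop))
    message(sprintf("build_profiles: dropped %d all-zero profile row(s)", sum(drop)))
  profiles <- profiles[!drop, , drop = FALSE]
  protein <- protein[!drop]
  replicate <- replicate[!drop]
  profiles <- switch(norm,
    sum = profiles / rowSums(profiles),
    max = profiles / apply(profiles, 1, max))
  structure(list(profiles = profiles, protein = protein,
                 replicate = replicate, days = days,
                 n_dropped = sum(drop), norm = norm),
            class = "profile_set")
}

#' K-means clustering of temporal profiles
#'
#' Standard Euclidean k-means on the normalized profiles, keeping the best
#' of \code{restarts} random initializations by total within-cluster sum of
#' squares. Deterministic given \code{(seed, restarts)}.
#'
#' @param p a \code{\link{build_profiles}} result.
#' @param k number of clusters (default 20, the profile-archetype
#'   resolution used for the differentiation time course).
#' @param seed integer seed for the initializations.
#' @param restarts number of random starts (default 10).
#' @param iter_max iteration cap per start.
#' @return object of class \code{cluster_model}: list with \code{k},
#'   \code{assignment} (named by profile row), \code{centroids} (k x days),
#'   \code{inertia}, \code{sizes}, \code{protein}, \code{replicate},
#'   \code{days}, \code{seed}, \code{restarts}.
#' @export
kmeans_profiles <- function(p, k = 20, seed = 1, restarts = 10,
                            iter_max = 300) {
  stopifnot(inherits(p, "profile_set"))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(p$profiles))
    stop(sprintf("k (%d) exceeds the number of profile rows (%d)",
                 k, nrow(p$profiles)))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(p$profiles, centers = k, nstart = restarts,
                  iter.max = iter_max))
  if (!is.null(km$ifault) && km$ifault == 4)
    message("kmeans_profiles: iteration cap reached in at least one start")
  structure(list(k = k,
                 assignment = stats::setNames(km$cluster, rownames(p$profiles)),
                 centroids = km$centers,
                 inertia = km$tot.withinss,
                 sizes = km$size,
                 protein = p$protein, replicate = p$replicate,
                 days = p$days, seed = seed, restarts = restarts),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d over %d profiles, inertia = %.4g\n",
              x$k, length(x$assignment), x$inertia))
  invisible(x)
}

#' Replicate composition of each cluster
#'
#' Fraction of each cluster's member rows contributed by each replicate.
#' With concordant replicates every cluster should contain roughly the same
#' share of rows from each replicate; strong deviations flag a cluster
#' driven by a single experiment.
#'
#' @param model a \code{\link{kmeans_profiles}} result.
#' @return matrix (clusters x replicates) of fractions summing to 1 per
#'   non-empty cluster, with member counts in attribute \code{counts};
#'   empty clusters get a zero row.
#' @export
replicate_composition <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  reps <- sort(unique(model$replicate))
  counts <- t(vapply(seq_len(model$k), function(cl) {
    vapply(reps, function(r)
      sum(model$assignment == cl & model$replicate == r), numeric(1))
  }, numeric(length(reps))))
  dimnames(counts) <- list(cluster = seq_len(model$k),
                           replicate = as.character(reps))
  total <- rowSums(counts)
  frac <- counts / ifelse(total == 0, 1, total)
  if (any(total == 0))
    message("replicate_composition: empty cluster(s): ",
            paste(which(total == 0), collapse = ", "))
  attr(frac, "counts") <- counts
  frac
}

#' Map each cluster to its peak day
#'
#' The day at which a cluster's centroid is maximal; ties break toward the
#' earliest day.
#'
#' @param model a \code{\link{kmeans_profiles}} result.
#' @return list with \code{peak_day} (named numeric per cluster) and
#'   \code{by_day} (day label -> integer cluster ids).
#' @export
peak_day_clusters <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  idx <- apply(model$centroids, 1, which.max)  # which.max: first = earliest day
  peak <- stats::setNames(model$days[idx], seq_len(model$k))
  by_day <- lapply(model$days, function(d) unname(which(peak == d)))
  names(by_day) <- as.character(model$days)
  list(peak_day = peak, by_day = by_day)
}

#' Top shared proteins of a cluster
#'
#' Proteins whose profile rows fall in the given cluster for every
#' replicate in which the protein is present ("shared" across replicates),
#' ranked by mean abundance over all samples and truncated to \code{n}.
#' Each reported protein's per-day expression is normalized by its maximum
#' day value.
#'
#' @param model a \code{\link{kmeans_profiles}} result.
#' @param m the \code{\link{abundance_matrix}} the profiles came from.
#' @param meta its sample metadata.
#' @param cluster integer cluster id.
#' @param n maximum number of proteins returned (default 10).
#' @return data frame: \code{protein}, \code{mean_abundance}, then one
#'   column per day with expression normalized to max 1.
#' @export
top_shared_proteins <- function(model, m, meta, cluster, n = 10) {
  stopifnot(inherits(model, "cluster_model"), inherits(m, "abundance_matrix"))
  meta <- validate_meta(m, meta)
  in_cluster <- tapply(model$assignment == cluster, model$protein, all)
  shared <- names(in_cluster)[in_cluster]
  if (!length(shared)) {
    message(sprintf("top_shared_proteins: no shared proteins in cluster %d", cluster))
    empty <- data.frame(protein = character(0), mean_abundance = numeric(0))
    for (d in model$days) empty[[sprintf("d%g", d)]] <- numeric(0)
    return(empty)
  }
  mean_ab <- rowMeans(m$values[shared, , drop = FALSE])
  shared <- shared[order(-mean_ab, shared)]
  if (length(shared) < n)
    message(sprintf("top_shared_proteins: only %d shared protein(s) in cluster %d",
                    length(shared), cluster))
  shared <- shared[seq_len(min(n, length(shared)))]
  day_expr <- vapply(model$days, function(d)
    rowMeans(m$values[shared, meta$day == d, drop = FALSE]),
    numeric(length(shared)))
  day_expr <- matrix(day_expr, nrow = length(shared),
                     dimnames = list(shared, sprintf("d%g", model$days)))
  day_expr <- day_expr / apply(day_expr, 1, max)
  out <- data.frame(protein = shared, mean_abundance = mean_ab[shared],
                    day_expr, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected agreement of random
#' labelings.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
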