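#' Configuration for the synthetic LFQ time-course generator
#'
#' Bundles and validates the parameters of
#' \code{\link{simulate_timecourse}}. Defaults emulate the study design the
#' package targets: a 5-point differentiation time course (days 0, 3, 5, 7,
#' 10) measured in 3 replicates, with day-specific marker proteins planted
#' at a 2 log2-unit mean shift.
#'
#' Intensity defaults describe a typical whole-lysate LFQ experiment with
#' match-between-runs: log2 intensities centred at \code{base_log_mean} with
#' a dynamic-range spread \code{base_log_sd}, replicate noise
#' \code{noise_sd} (~18\% CV), left-censored missingness at rate
#' \code{missing_rate_at_median} for a protein of median intensity, and
#' modest per-sample loading distortions (\code{sample_scale_sd}, log2 sd).
#'
#' @param n_proteins number of proteins.
#' @param days strictly increasing numeric day labels.
#' @param n_replicates replicates per day.
#' @param markers_per_day day-specific marker proteins planted per day
#'   (requires \code{markers_per_day * length(days) <= n_proteins}).
#' @param marker_effect log2 mean shift of a marker at its day.
#' @param base_log_mean,base_log_sd log2-intensity law across proteins.
#' @param noise_sd log2 replicate (within-protein) noise sd.
#' @param missing_rate_at_median missingness probability for an entry whose
#'   true log2 intensity equals the global median.
#' @param censoring_steepness logistic slope of missingness per log2 unit
#'   below the median (larger = sharper detection limit).
#' @param sample_scale_sd log2 sd of per-sample multiplicative distortions.
#' @param peptide_count_mean mean unique-peptide count; counts are drawn as
#'   \code{1 + Poisson(peptide_count_mean - 1)} so a small fraction falls
#'   below the master-protein filter.
#' @param seed integer seed governing all draws.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 2000,
                       days = c(0, 3, 5, 7, 10),
                       n_replicates = 3,
                       markers_per_day = 50,
                       marker_effect = 2,
                       base_log_mean = 20,
                       base_log_sd = 2,
                       noise_sd = 0.25,
                       missing_rate_at_median = 0.05,
                       censoring_steepness = 1,
                       sample_scale_sd = 0.25,
                       peptide_count_mean = 6,
                       seed = 1) {
  cfg <- list(n_proteins = n_proteins, days = days,
              n_replicates = n_replicates, markers_per_day = markers_per_day,
              marker_effect = marker_effect, base_log_mean = base_log_mean,
              base_log_sd = base_log_sd, noise_sd = noise_sd,
              missing_rate_at_median = missing_rate_at_median,
              censoring_steepness = censoring_steepness,
              sample_scale_sd = sample_scale_sd,
              peptide_count_mean = peptide_count_mean, seed = seed)
  if (n_proteins < 1 || n_replicates < 1 || length(days) < 1)
    stop("configuration error: counts must be positive")
  if (any(diff(days) <= 0)) stop("configuration error: days must be strictly increasing")
  if (missing_rate_at_median < 0 || missing_rate_at_median > 1)
    stop("configuration error: missing_rate_at_median must be in [0, 1]")
  if (markers_per_day < 0 || markers_per_day * length(days) > n_proteins)
    stop("configuration error: markers_per_day * |days| must be <= n_proteins")
  if (noise_sd < 0 || base_log_sd < 0 || sample_scale_sd < 0)
    stop("configuration error: sds must be >= 0")
  if (peptide_count_mean < 1)
    stop("configuration error: peptide_count_mean must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate an LFQ-like differentiation time course with planted truth
#'
#' Generates a proteins x samples intensity matrix with day-specific marker
#' proteins, left-censored missingness, per-sample scale distortions, and
#' unique-peptide counts, together with the ground truth needed to verify
#' every downstream stage.
#'
#' Mechanics: each protein gets a base log2 intensity from
#' \code{N(base_log_mean, base_log_sd)}; marker proteins are drawn from the
#' upper half of that law (a day-specific protein must be quantifiable to be
#' observable as such) and receive \code{marker_effect} extra log2 units in
#' all samples of their day. Replicate noise is added, entries are censored
#' with logistic probability decreasing in true log2 intensity (rate
#' \code{missing_rate_at_median} at the global median), and each sample is
#' multiplied by a log-normal scale factor. Censoring is driven by the true
#' (pre-distortion) intensity so the distortion acts as a pure measurement
#' gain.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{matrix} (an \code{\link{abundance_matrix}} with
#'   missing entries as \code{NA}), \code{meta} (sample metadata), and
#'   \code{truth}: \code{marker_day} (named, markers only), \code{archetype}
#'   (per protein: \code{"peak_d<day>"} or \code{"flat"}),
#'   \code{sample_scales}, \code{log2_true} (pre-censoring, pre-distortion
#'   log2 matrix), and the \code{config}.
#' @export
simulate_timecourse <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  days <- config$days
  R <- config$n_replicates
  P <- config$n_proteins
  day_of <- rep(days, each = R)
  rep_of <- rep(seq_len(R), times = length(days))
  samples <- sprintf("d%g_r%d", day_of, rep_of)
  proteins <- sprintf("P%05d", seq_len(P))

  n_mark <- config$markers_per_day * length(days)
  marker_day <- rep(NA_real_, P)
  if (n_mark > 0)
    marker_day[seq_len(n_mark)] <- rep(days, each = config$markers_per_day)

  mu <- stats::rnorm(P, config$base_log_mean, config$base_log_sd)
  is_mark <- !is.na(marker_day)
  mu[is_mark] <- config$base_log_mean +
    abs(stats::rnorm(sum(is_mark), 0, config$base_log_sd))

  L <- matrix(mu, P, length(samples)) +
    matrix(stats::rnorm(P * length(samples), 0, config$noise_sd),
           P, length(samples))
  shift <- outer(marker_day, day_of,
                 function(m, d) ifelse(!is.na(m) & m == d, config$marker_effect, 0))
  L <- L + shift
  dimnames(L) <- list(proteins, samples)

  p_miss <- stats::plogis(stats::qlogis(config$missing_rate_at_median) -
                            config$censoring_steepness * (L - stats::median(L)))
  miss <- matrix(stats::runif(length(L)) < p_miss, P, length(samples),
                 dimnames = dimnames(L))

  log2_scales <- stats::rnorm(length(samples), 0, config$sample_scale_sd)
  scales <- stats::setNames(2^log2_scales, samples)
  values <- sweep(2^L, 2, scales, "*")
  values[miss] <- NA

  up <- 1L + stats::rpois(P, config$peptide_count_mean - 1)
  m <- abundance_matrix(values, unique_peptides = up, missing = miss)
  meta <- data.frame(sample_id = samples, day = day_of, replicate = rep_of,
                     condition = "differentiation", stringsAsFactors = FALSE)
  truth <- list(
    marker_day = stats::setNames(marker_day[is_mark], proteins[is_mark]),
    archetype = stats::setNames(
      ifelse(is_mark, sprintf("peak_d%g", marker_day), "flat"), proteins),
    sample_scales = scales,
    log2_true = L,
    config = config)
  list(matrix = m, meta = meta, truth = truth)
}

#' Simulate a correlated pair of mean-abundance vectors with outliers
#'
#' Emulates the endpoint comparison of a derived-cell proteome (vector A)
#' against a primary-cell reference (vector B): paired log2 mean abundances
#' drawn from a bivariate normal law with population correlation
#' \code{target_r}, plus \code{n_outliers} planted discordant proteins.
#'
#' Outliers model a dominant, highly abundant protein overexpressed in the
#' derived cells relative to the reference (the vimentin analog): they are
#' planted at the most abundant proteins of vector A and receive a
#' \code{-outlier_shift} log2 shift in vector B only.
#'
#' @param n_proteins number of proteins (>= 3).
#' @param target_r planned population correlation, in [-1, 1].
#' @param n_outliers number of planted discordant proteins
#'   (< \code{n_proteins}).
#' @param outlier_shift log2 magnitude of the discordant shift.
#' @param seed integer seed.
#' @param base_log_mean,base_log_sd marginal law of both vectors.
#' @return list with named vectors \code{a} and \code{b} and \code{truth}
#'   recording \code{outlier_proteins} and \code{target_r}.
#' @export
simulate_reference_pair <- function(n_proteins, target_r, n_outliers = 0,
                                    outlier_shift = 0, seed = 1,
                                    base_log_mean = 20, base_log_sd = 2) {
  if (n_proteins < 3) stop("n_proteins must be >= 3")
  if (abs(target_r) > 1) stop("target_r must be in [-1, 1]")
  if (n_outliers >= n_proteins) stop("n_outliers must be < n_proteins")
  set.seed(seed)
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  z1 <- stats::rnorm(n_proteins)
  z2 <- stats::rnorm(n_proteins)
  a <- base_log_mean + base_log_sd * z1
  b <- base_log_mean + base_log_sd *
    (target_r * z1 + sqrt(1 - target_r^2) * z2)
  names(a) <- names(b) <- proteins
  outliers <- character(0)
  if (n_outliers > 0) {
    outliers <- proteins[order(a, decreasing = TRUE)[seq_len(n_outliers)]]
    b[outliers] <- b[outliers] - outlier_shift
  }
  list(a = a, b = b,
       truth = list(outlier_proteins = outliers, target_r = target_r))
}

#' Simulate paired two-condition endpoint and reference matrices
#'
#' Builds the inputs of the reference-comparison stage: a derived-cell
#' endpoint matrix (two culture conditions x two endpoint days x replicates)
#' and a primary-cell reference matrix (one day per condition, one sample
#' per donor), sharing a protein universe. Per (condition, day), the derived
#' protein-level log2 means are drawn correlated at \code{target_r[cond]}
#' with the condition's reference means. One vimentin-analog protein -- of
#' high (90th percentile) but not extreme reference abundance -- is
#' discordant: its derived-side mean is raised by \code{outlier_shift} log2
#' units in every condition and day, emulating a dominant protein
#' overexpressed in the derived cells relative to the primary reference.
#'
#' Sample-level intensities add replicate noise, per-sample scale
#' distortions and left-censored missingness exactly as in
#' \code{\link{simulate_timecourse}}. The planted correlation lives on the
#' latent log2 scale (recorded in the truth); the correlation measured
#' through the pipeline is attenuated by censoring and replicate noise, as
#' in real data. The outlier's influence is assessed on the normalized raw
#' abundance scale, where an abundant protein carries its full leverage.
#'
#' @param n_proteins number of proteins.
#' @param target_r named correlation per condition.
#' @param derived_days endpoint day labels of the derived dataset.
#' @param reference_day day label of the reference dataset.
#' @param n_replicates replicates (derived) / donors (reference).
#' @param outlier_shift log2 discordant shift of the vimentin analog.
#' @param seed integer seed.
#' @param config intensity-law parameters reused from
#'   \code{\link{sim_config}} (only the intensity/noise/censoring fields are
#'   used).
#' @return list with \code{derived} and \code{reference} (each a list of
#'   \code{matrix} and \code{meta}) and \code{truth} (\code{outlier_protein},
#'   \code{target_r}, per-condition log2 mean vectors).
#' @export
simulate_condition_matrices <- function(n_proteins = 2000,
                                        target_r = c(NM = 0.8, OM = 0.6),
                                        derived_days = c(10, 17),
                                        reference_day = 14,
                                        n_replicates = 3,
                                        outlier_shift = 8,
                                        seed = 1,
                                        config = sim_config(seed = seed)) {
  if (is.null(names(target_r)) || any(!nzchar(names(target_r))))
    stop("target_r must be a named vector of per-condition correlations")
  if (any(abs(target_r) > 1)) stop("target_r must be in [-1, 1]")
  set.seed(seed)
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  conditions <- names(target_r)

  # Reference log2 means per condition. The vimentin analog is a protein of
  # high (90th percentile) but not extreme reference abundance whose derived
  # expression is inflated by outlier_shift: dominant leverage on the raw
  # abundance scale, and discordant, so its removal raises the correlation.
  zb <- lapply(conditions, function(cc) stats::rnorm(n_proteins))
  names(zb) <- conditions
  b <- lapply(conditions, function(cc)
    config$base_log_mean + config$base_log_sd * zb[[cc]])
  names(b) <- conditions
  oi <- order(Reduce(`+`, b))[ceiling(0.9 * n_proteins)]
  outlier <- proteins[oi]
  a <- list()
  for (cc in conditions) {
    r <- target_r[[cc]]
    a[[cc]] <- lapply(derived_days, function(d) {
      mu <- config$base_log_mean + config$base_log_sd *
        (r * zb[[cc]] + sqrt(1 - r^2) * stats::rnorm(n_proteins))
      mu[oi] <- mu[oi] + outlier_shift
      mu
    })
    names(a[[cc]]) <- sprintf("d%g", derived_days)
  }

  build <- function(mean_cols, meta) {
    L <- do.call(cbind, mean_cols) +
      matrix(stats::rnorm(n_proteins * nrow(meta), 0, config$noise_sd),
             n_proteins, nrow(meta))
    dimnames(L) <- list(proteins, meta$sample_id)
    p_miss <- stats::plogis(stats::qlogis(config$missing_rate_at_median) -
                              config$censoring_steepness * (L - stats::median(L)))
    miss <- matrix(stats::runif(length(L)) < p_miss, nrow(L), ncol(L),
                   dimnames = dimnames(L))
    scales <- 2^stats::rnorm(nrow(meta), 0, config$sample_scale_sd)
    values <- sweep(2^L, 2, scales, "*")
    values[miss] <- NA
    up <- 1L + stats::rpois(n_proteins, config$peptide_count_mean - 1)
    abundance_matrix(values, unique_peptides = up, missing = miss)
  }

  derived_meta <- do.call(rbind, lapply(conditions, function(cc) {
    do.call(rbind, lapply(derived_days, function(d) {
      data.frame(sample_id = sprintf("%s_d%g_r%d", cc, d, seq_len(n_replicates)),
                 day = d, replicate = seq_len(n_replicates), condition = cc,
                 stringsAsFactors = FALSE)
    }))
  }))
  derived_cols <- unlist(lapply(conditions, function(cc)
    lapply(derived_days, function(d)
      matrix(rep(a[[cc]][[sprintf("d%g", d)]], n_replicates),
             n_proteins, n_replicates))), recursive = FALSE)
  derived_m <- build(derived_cols, derived_meta)

  reference_meta <- do.call(rbind, lapply(conditions, function(cc) {
    data.frame(sample_id = sprintf("ref_%s_donor%d", cc, seq_len(n_replicates)),
               day = reference_day, replicate = seq_len(n_replicates),
               condition = cc, stringsAsFactors = FALSE)
  }))
  reference_cols <- lapply(conditions, function(cc)
    matrix(rep(b[[cc]], n_replicates), n_proteins, n_replicates))
  reference_m <- build(reference_cols, reference_meta)

  list(derived = list(matrix = derived_m, meta = derived_meta),
       reference = list(matrix = reference_m, meta = reference_meta),
       truth = list(outlier_protein = outlier, target_r = target_r,
                    derived_log2_means = a, reference_log2_means = b))
}
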