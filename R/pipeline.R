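#' Configuration for an end-to-end pipeline run
#'
#' Collects stage toggles and stage parameters with validated defaults.
#' A single integer \code{seed} is fanned out to fixed per-stage substreams
#' (simulation, clustering, reference simulation) so a run is reproducible
#' from the config alone.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @param stages character subset of
#'   \code{c("simulate", "preprocess", "dayspec", "cluster", "diff",
#'   "compare")}; stages not listed are skipped. \code{simulate} generates
#'   synthetic inputs; alternatively give \code{matrix_path}/\code{meta_path}.
#' @param matrix_path,meta_path optional TSV inputs used instead of the
#'   simulate stage.
#' @param sim a \code{\link{sim_config}} for the simulate stage.
#' @param min_unique_peptides,normalize preprocess parameters.
#' @param threshold,scan_grid,scan_tol day-specificity parameters.
#' @param k,restarts clustering parameters.
#' @param p_cutoff,lfc_cutoff,pseudocount differential-abundance parameters.
#' @param compare_target_r,compare_outlier_shift reference-comparison
#'   simulation parameters.
#' @return a validated list of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       stages = c("simulate", "preprocess", "dayspec",
                                  "cluster", "diff", "compare"),
                       matrix_path = NULL, meta_path = NULL,
                       sim = sim_config(seed = seed),
                       min_unique_peptides = 3, normalize = TRUE,
                       threshold = 1.5,
                       scan_grid = seq(0.5, 3, by = 0.1), scan_tol = 0.05,
                       k = 20, restarts = 10,
                       p_cutoff = 0.05, lfc_cutoff = 1, pseudocount = 1,
                       compare_target_r = c(NM = 0.8, OM = 0.6),
                       compare_outlier_shift = 8) {
  known <- c("simulate", "preprocess", "dayspec", "cluster", "diff", "compare")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (!"simulate" %in% stages &&
      (is.null(matrix_path) || is.null(meta_path)))
    stop("without the simulate stage, matrix_path and meta_path are required")
  if (threshold <= 0 || p_cutoff <= 0 || pseudocount <= 0)
    stop("cutoffs and pseudocount must be positive")
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 matrix_path = matrix_path, meta_path = meta_path, sim = sim,
                 min_unique_peptides = min_unique_peptides,
                 normalize = normalize, threshold = threshold,
                 scan_grid = scan_grid, scan_tol = scan_tol, k = k,
                 restarts = restarts, p_cutoff = p_cutoff,
                 lfc_cutoff = lfc_cutoff, pseudocount = pseudocount,
                 compare_target_r = compare_target_r,
                 compare_outlier_shift = compare_outlier_shift),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in order -- simulate (or read), preprocess,
#' day specificity, trajectory clustering, adjacent-day differential
#' abundance, reference comparison -- writing every stage's tables as TSV
#' under \code{out_dir} and a JSON manifest recording the configuration,
#' seed, package version, stage status and MD5 checksums of all outputs.
#' Re-running the same config reproduces byte-identical TSVs.
#'
#' @param config a \code{\link{run_config}}.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  status <- stats::setNames(
    rep("skipped", 6),
    c("simulate", "preprocess", "dayspec", "cluster", "diff", "compare"))
  files <- character(0)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      sim <<- simulate_timecourse(config$sim)
      write_matrix(sim$matrix, out("matrix.tsv"), sim$meta, out("meta.tsv"))
      truth_tab <- data.frame(
        protein = names(sim$truth$archetype),
        archetype = sim$truth$archetype,
        marker_day = sim$truth$marker_day[names(sim$truth$archetype)],
        stringsAsFactors = FALSE)
      write_tsv(truth_tab, out("truth_proteins.tsv"))
      write_tsv(data.frame(sample_id = names(sim$truth$sample_scales),
                           scale = sim$truth$sample_scales),
                out("truth_sample_scales.tsv"))
      files <<- c(files, out("matrix.tsv"), out("meta.tsv"),
                  out("truth_proteins.tsv"), out("truth_sample_scales.tsv"))
      status["simulate"] <<- "completed"
    })
    input <- list(matrix = sim$matrix, meta = sim$meta)
  } else {
    input <- read_matrix(config$matrix_path, config$meta_path)
  }

  prep <- NULL
  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", function() {
      prep <<- preprocess(input$matrix, input$meta,
                          min_unique_peptides = config$min_unique_peptides,
                          normalize = config$normalize)
      write_matrix(prep$matrix, out("normalized_matrix.tsv"))
      if (!is.null(prep$factors))
        write_tsv(data.frame(sample_id = names(prep$factors),
                             factor = prep$factors),
                  out("scale_factors.tsv"))
      writeLines(prep$log, out("preprocess_log.txt"))
      files <<- c(files, out("normalized_matrix.tsv"),
                  if (!is.null(prep$factors)) out("scale_factors.tsv"),
                  out("preprocess_log.txt"))
      status["preprocess"] <<- "completed"
    })
  } else {
    prep <- list(matrix = replace_missing_with_zero(input$matrix),
                 meta = validate_meta(input$matrix, input$meta))
  }

  if ("dayspec" %in% config$stages) {
    run_stage("dayspec", function() {
      z <- zscore_abundance(prep$matrix, prep$meta)
      zs <- data.frame(protein = rownames(z$zscores), z$zscores,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(zs, out("zscores.tsv"))
      files <<- c(files, out("zscores.tsv"))
      scan <- scan_threshold(z, config$scan_grid, config$scan_tol)
      write_tsv(as.data.frame(scan), out("threshold_scan.tsv"))
      files <<- c(files, out("threshold_scan.tsv"))
      sets <- day_specific_sets(z, config$threshold)
      for (d in names(sets$sets)) {
        f <- out("day_specific_d%s.tsv", d)
        write_tsv(data.frame(protein = sets$sets[[d]]), f)
        files <<- c(files, f)
      }
      # self-check enrichment against planted marker groups when available
      if (!is.null(sim)) {
        ann <- split(names(sim$truth$marker_day),
                     sprintf("marker_d%g", sim$truth$marker_day))
        bg <- rownames(prep$matrix$values)
        tabs <- lapply(names(sets$sets), function(d) {
          s <- intersect(sets$sets[[d]], bg)
          if (!length(s)) return(NULL)
          cbind(day = d, enrich(s, ann, bg))
        })
        write_tsv(do.call(rbind, tabs), out("enrichment.tsv"))
        files <<- c(files, out("enrichment.tsv"))
      }
      status["dayspec"] <<- "completed"
    })
  }

  if ("cluster" %in% config$stages) {
    run_stage("cluster", function() {
      prof <- build_profiles(prep$matrix, prep$meta)
      model <- kmeans_profiles(prof, k = config$k, seed = config$seed + 1L,
                               restarts = config$restarts)
      write_tsv(data.frame(row = names(model$assignment),
                           protein = model$protein,
                           replicate = model$replicate,
                           cluster = model$assignment),
                out("cluster_assignments.tsv"))
      write_tsv(data.frame(cluster = seq_len(model$k), model$centroids,
                           check.names = FALSE),
                out("cluster_centroids.tsv"))
      comp <- replicate_composition(model)
      write_tsv(data.frame(cluster = seq_len(model$k), comp,
                           check.names = FALSE),
                out("cluster_composition.tsv"))
      peaks <- peak_day_clusters(model)
      write_tsv(data.frame(cluster = seq_len(model$k),
                           peak_day = peaks$peak_day),
                out("cluster_peak_days.tsv"))
      top <- do.call(rbind, lapply(seq_len(model$k), function(cl) {
        tt <- top_shared_proteins(model, prep$matrix, prep$meta, cl)
        if (nrow(tt)) cbind(cluster = cl, tt) else NULL
      }))
      write_tsv(top, out("cluster_top_shared.tsv"))
      files <<- c(files, out("cluster_assignments.tsv"),
                  out("cluster_centroids.tsv"), out("cluster_composition.tsv"),
                  out("cluster_peak_days.tsv"), out("cluster_top_shared.tsv"))
      status["cluster"] <<- "completed"
    })
  }

  if ("diff" %in% config$stages) {
    run_stage("diff", function() {
      logm <- log_transform(prep$matrix, config$pseudocount)
      days <- sort(unique(prep$meta$day))
      pairs <- cbind(days[-length(days)], days[-1])
      if (length(days) > 2) pairs <- rbind(pairs, c(days[1], days[length(days)]))
      for (i in seq_len(nrow(pairs))) {
        res <- moderated_t_test(logm, prep$meta, pairs[i, 1], pairs[i, 2],
                                p_cutoff = config$p_cutoff,
                                lfc_cutoff = config$lfc_cutoff)
        res <- res[order(res$p_adjusted, res$p), , drop = FALSE]
        f <- out("diff_d%g_vs_d%g.tsv", pairs[i, 1], pairs[i, 2])
        write_tsv(res, f)
        files <<- c(files, f)
      }
      status["diff"] <<- "completed"
    })
  }

  if ("compare" %in% config$stages) {
    run_stage("compare", function() {
      pair <- simulate_condition_matrices(
        n_proteins = config$sim$n_proteins,
        target_r = config$compare_target_r,
        outlier_shift = config$compare_outlier_shift,
        seed = config$seed + 2L,
        config = config$sim)
      der <- preprocess(pair$derived$matrix, pair$derived$meta,
                        min_unique_peptides = 0)
      ref <- preprocess(pair$reference$matrix, pair$reference$meta,
                        min_unique_peptides = 0)
      cmp <- compare_conditions(der, ref, log2 = TRUE)
      write_tsv(cmp$reports, out("comparison_reports.tsv"))
      files <<- c(files, out("comparison_reports.tsv"))
      for (key in names(cmp$details)) {
        inf <- cmp$details[[key]]$influence
        inf <- inf[order(-abs(inf$delta_r), inf$protein), , drop = FALSE]
        f <- out("influence_%s.tsv", key)
        write_tsv(utils::head(inf, 50), f)
        files <<- c(files, f)
      }
      status["compare"] <<- "completed"
    })
  }

  manifest <- list(
    package = "stemtrace",
    version = as.character(utils::packageVersion("stemtrace")),
    seed = config$seed,
    stages = as.list(status),
    config = config[setdiff(names(config), "out_dir")],
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
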