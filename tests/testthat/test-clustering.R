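test_that("profiles are unit-sum per row and all-zero rows are dropped", {
  vals <- rbind(rep(2, 6),                # flat -> uniform profile
                c(0, 0, 0, 0, 0, 0),      # all-zero -> dropped
                c(4, 4, 0, 0, 2, 2))
  tc <- tiny_timecourse(vals, days = c(0, 3, 5), n_replicates = 2)
  expect_message(prof <- build_profiles(tc$matrix, tc$meta), "dropped 2")
  expect_equal(prof$n_dropped, 2)
  expect_equal(nrow(prof$profiles), 3 * 2 - 2)
  expect_equal(unname(rowSums(prof$profiles)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(prof$profiles["P01.r1", ]), rep(1 / 3, 3))
  # P P3 replicate 1 takes samples d0_r1, d3_r1, d5_r1 = 4, 0, 2
  expect_equal(unname(prof$profiles["P03.r1", ]), c(4, 0, 2) / 6)
  # unit-max option
  prof_max <- build_profiles(tc$matrix, tc$meta, norm = "max")
  expect_equal(unname(apply(prof_max$profiles, 1, max)), rep(1, 4))
  # complete data: exactly P * R rows
  tc2 <- tiny_timecourse(matrix(1:12 * 1.0, 2, 6), days = c(0, 3, 5),
                         n_replicates = 2)
  expect_equal(nrow(build_profiles(tc2$matrix, tc2$meta)$profiles), 2 * 2)
})

test_that("missing (day, replicate) combinations are an error", {
  tc <- tiny_timecourse(matrix(1, 2, 6), days = c(0, 3, 5), n_replicates = 2)
  meta <- tc$meta
  meta$replicate[meta$sample_id == "d3_r2"] <- 1   # no (d3, r2) cell left
  expect_error(build_profiles(tc$matrix, meta), "d3, r2")
})

test_that("k-means recovers two well-separated archetypes exactly", {
  set.seed(77)
  early <- c(0.8, 0.1, 0.05, 0.03, 0.02)
  late <- rev(early)
  prof <- rbind(t(replicate(10, early + runif(5, 0, 0.01))),
                t(replicate(10, late + runif(5, 0, 0.01))))
  prof <- prof / rowSums(prof)
  rownames(prof) <- sprintf("P%02d.r1", 1:20)
  p <- structure(list(profiles = prof, protein = sprintf("P%02d", 1:20),
                      replicate = rep(1, 20), days = c(0, 3, 5, 7, 10),
                      n_dropped = 0, norm = "sum"), class = "profile_set")
  model <- kmeans_profiles(p, k = 2, seed = 1)
  truth <- rep(c("early", "late"), each = 10)
  expect_equal(adjusted_rand_index(truth, model$assignment), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(adjusted_rand_index(truth, model$assignment),
                 mclust::adjustedRandIndex(truth, model$assignment))

  # k = 1: one cluster, centroid = mean profile
  m1 <- kmeans_profiles(p, k = 1, seed = 1)
  expect_true(all(m1$assignment == 1))
  expect_equal(unname(m1$centroids[1, ]), unname(colMeans(prof)))

  # restarts can only improve the objective
  m10 <- kmeans_profiles(p, k = 2, seed = 5, restarts = 10)
  m1r <- kmeans_profiles(p, k = 2, seed = 5, restarts = 1)
  expect_lte(m10$inertia, m1r$inertia)

  expect_error(kmeans_profiles(p, k = 21), "exceeds")
})

test_that("clustering is deterministic under a fixed seed", {
  sim <- simulate_timecourse(sim_config(n_proteins = 120, markers_per_day = 15, seed = 31))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  prof <- build_profiles(pp$matrix, pp$meta)
  m1 <- kmeans_profiles(prof, k = 6, seed = 2)
  m2 <- kmeans_profiles(prof, k = 6, seed = 2)
  expect_identical(m1$assignment, m2$assignment)
  expect_identical(m1$centroids, m2$centroids)
})

test_that("replicate composition counts member fractions per cluster", {
  model <- structure(list(k = 2,
                          assignment = c(a = 1, b = 1, c = 1, d = 1, e = 2),
                          replicate = c(1, 1, 2, 3, 1),
                          protein = letters[1:5],
                          centroids = matrix(0, 2, 2), days = c(0, 3)),
                     class = "cluster_model")
  comp <- replicate_composition(model)
  expect_equal(unname(comp[1, ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(comp[2, ]), c(1, 0, 0))
  expect_equal(unname(rowSums(comp)), c(1, 1))
})

test_that("peak-day mapping takes the centroid argmax with earliest-day ties", {
  cents <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
                 rep(0.2, 5),
                 c(0.1, 0.1, 0.2, 0.2, 0.4))
  model <- structure(list(k = 3, centroids = cents, days = c(0, 3, 5, 7, 10),
                          assignment = integer(0), replicate = integer(0),
                          protein = character(0)), class = "cluster_model")
  peaks <- peak_day_clusters(model)
  expect_equal(unname(peaks$peak_day), c(0, 0, 10))  # uniform row -> earliest
  expect_equal(peaks$by_day[["0"]], c(1, 2))
})

test_that("five planted archetypes give a peak-day bijection and balanced replicates", {
  sim <- simulate_timecourse(sim_config(n_proteins = 250, markers_per_day = 50,
                                        seed = 4))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  prof <- build_profiles(pp$matrix, pp$meta)
  model <- kmeans_profiles(prof, k = 5, seed = 14)
  ari <- adjusted_rand_index(sim$truth$archetype[model$protein],
                             model$assignment)
  expect_gte(ari, 0.8)
  peaks <- peak_day_clusters(model)
  expect_setequal(unname(peaks$peak_day), c(0, 3, 5, 7, 10))
  comp <- replicate_composition(model)
  big <- rowSums(attr(comp, "counts")) >= 30
  expect_lt(max(abs(comp[big, ] - 1 / 3)), 0.15)
})

test_that("top shared proteins require cluster agreement across replicates", {
  # P1 agrees across replicates (cluster of early peak); P2 does not
  vals <- rbind(c(9, 9, 1, 1, 1, 1),     # P1: early in both replicates
                c(9, 1, 1, 9, 1, 1),     # P2: early in r1, mid in r2
                c(8, 8, 1, 1, 1, 1))     # P3: early in both
  tc <- tiny_timecourse(vals, days = c(0, 3, 5), n_replicates = 2)
  prof <- build_profiles(tc$matrix, tc$meta)
  model <- kmeans_profiles(prof, k = 2, seed = 3)
  cl_p1 <- unname(model$assignment["P01.r1"])
  top <- top_shared_proteins(model, tc$matrix, tc$meta, cl_p1, n = 10)
  expect_true(all(c("P01", "P03") %in% top$protein))
  expect_false("P02" %in% top$protein)
  # ranked by mean abundance: P1 (mean 3.67) above P3 (3.33)
  expect_equal(top$protein[1:2], c("P01", "P03"))
  # per-day expression normalized to max 1 at exactly one day
  daycols <- as.matrix(top[, c("d0", "d3", "d5")])
  expect_equal(unname(apply(daycols, 1, max)), rep(1, nrow(top)))
  expect_true(all(rowSums(daycols == 1) == 1))
})
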