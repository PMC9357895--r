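test_that("day z-scores match hand arithmetic and the sigma-zero convention", {
  # day0 = {10,10,10}, day3 = {0,0,0}: overall mean 5, sd sqrt(30)
  tc <- tiny_timecourse(matrix(c(10, 10, 10, 0, 0, 0), 1, 6, byrow = TRUE),
                        days = c(0, 3), n_replicates = 3)
  z <- zscore_abundance(tc$matrix, tc$meta)
  expect_equal(unname(z$overall_mean), 5)
  expect_equal(unname(z$overall_sd), sqrt(30))
  expect_equal(unname(z$zscores[1, ]), c(5, -5) / sqrt(30), tolerance = 1e-12)

  # constant protein: Z = 0 everywhere
  tc2 <- tiny_timecourse(matrix(7, 2, 6), days = c(0, 3), n_replicates = 3)
  z2 <- zscore_abundance(tc2$matrix, tc2$meta)
  expect_true(all(z2$zscores == 0))
})

test_that("z-scores are scale-free and their day-weighted sum vanishes", {
  sim <- simulate_timecourse(sim_config(n_proteins = 150, markers_per_day = 20, seed = 17))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  z <- zscore_abundance(pp$matrix, pp$meta)
  # invariant to a global positive rescaling
  m10 <- pp$matrix; m10$values <- m10$values * 10
  z10 <- zscore_abundance(m10, pp$meta)
  expect_equal(z$zscores, z10$zscores, tolerance = 1e-9)
  # sum_d n_d * Z_jd = 0
  wsum <- z$zscores %*% z$n_per_day
  expect_lt(max(abs(wsum)), 1e-9)
})

test_that("day-specific sets obey the strict threshold and multiplicity count", {
  zs <- matrix(c(2.0, 0.1, -0.5, -0.8, -0.8,
                 1.6, 1.7, -1.0, -1.0, -1.0), 2, 5, byrow = TRUE,
               dimnames = list(c("A", "B"), c("0", "3", "5", "7", "10")))
  z <- structure(list(zscores = zs, days = c(0, 3, 5, 7, 10)),
                 class = "day_specificity")
  s <- day_specific_sets(z, 1.5)
  expect_identical(s$sets[["0"]], c("A", "B"))
  expect_identical(s$sets[["3"]], "B")
  expect_equal(s$multiplicity, c(A = 1L, B = 2L))
  # threshold above every Z empties all sets
  s2 <- day_specific_sets(z, 3)
  expect_true(all(lengths(s2$sets) == 0))
})

test_that("planted markers are recovered with high per-day precision and recall", {
  sim <- simulate_timecourse(sim_config(seed = 1))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  z <- zscore_abundance(pp$matrix, pp$meta)
  sets <- day_specific_sets(z, 1.5)
  for (d in sort(unique(sim$meta$day))) {
    called <- sets$sets[[as.character(d)]]
    truth <- names(sim$truth$marker_day)[sim$truth$marker_day == d]
    tp <- length(intersect(called, truth))
    expect_gte(tp / length(called), 0.9)
    expect_gte(tp / length(truth), 0.9)
  }
})

test_that("threshold scan is monotone and selects by the multiplicity rule", {
  sim <- simulate_timecourse(sim_config(n_proteins = 500, seed = 19))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  z <- zscore_abundance(pp$matrix, pp$meta)
  scan <- scan_threshold(z)
  expect_true(all(diff(scan$n_specific) <= 0))
  sel <- attr(scan, "selected")
  # brute-force recount at the selected threshold
  mult <- day_specific_sets(z, sel)$multiplicity
  mm <- mean(mult[mult > 0])
  expect_lte(mm, 1.05)
  # every smaller grid threshold violates the rule (sel is the smallest)
  smaller <- scan$threshold < sel
  expect_true(all(scan$mean_multiplicity[smaller] > 1.05, na.rm = TRUE))

  # single-day grouping makes every specific protein multiplicity-1,
  # so the smallest grid value is selected
  z1 <- z
  z1$zscores <- z1$zscores[, 1, drop = FALSE]
  s1 <- scan_threshold(z1, grid = c(0.5, 1, 1.5))
  expect_equal(attr(s1, "selected"), 0.5)
  # unattainable criterion falls back to the largest grid value with a warning
  zbad <- structure(list(zscores = matrix(2, 5, 2,
      dimnames = list(letters[1:5], c("0", "3")))), class = "day_specificity")
  expect_warning(sbad <- scan_threshold(zbad, grid = c(0.5, 1)), "largest")
  expect_equal(attr(sbad, "selected"), 1)
})

test_that("enrichment p-values equal exact hypergeometric tail sums", {
  bg <- sprintf("g%02d", 1:100)
  set <- bg[1:10]
  term <- bg[c(1:5, 50:54)]      # overlap 5, term size 10
  tab <- enrich(set, list(T1 = term), bg, min_term_size = 1)
  p_exact <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(tab$p, p_exact, tolerance = 1e-12)
  expect_equal(tab$overlap, 5)

  # term disjoint from the background is skipped
  tab2 <- enrich(set, list(T1 = term, OFF = c("zz1", "zz2", "zz3")), bg,
                 min_term_size = 1)
  expect_false("OFF" %in% tab2$term)

  # drawing the whole urn gives p = 1 for every term
  tab3 <- enrich(bg, list(T1 = term), bg, min_term_size = 1)
  expect_equal(tab3$p, 1)

  # adjusted p >= raw p and both in [0, 1]
  set.seed(30)
  ann <- lapply(1:20, function(i) sample(bg, 15))
  names(ann) <- sprintf("T%02d", 1:20)
  tab4 <- enrich(set, ann, bg)
  expect_true(all(tab4$p_adjusted >= tab4$p))
  expect_true(all(tab4$p_adjusted <= 1 & tab4$p >= 0))
})

test_that("enrichment recovers a planted annotation on synthetic markers", {
  sim <- simulate_timecourse(sim_config(n_proteins = 600, seed = 23))
  pp <- preprocess(sim$matrix, sim$meta, min_unique_peptides = 0)
  z <- zscore_abundance(pp$matrix, pp$meta)
  sets <- day_specific_sets(z, 1.5)
  ann <- split(names(sim$truth$marker_day),
               sprintf("marker_d%g", sim$truth$marker_day))
  bg <- rownames(pp$matrix$values)
  tab <- enrich(sets$sets[["0"]], ann, bg)
  expect_equal(tab$term[1], "marker_d0")
  expect_lt(tab$p_adjusted[1], 1e-10)
})

test_that("GMT files round-trip through the reader", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tg1\tg2\tg3",
               "T2\tsecond term\tg2\tg4"), f)
  gmt <- read_gmt(f)
  expect_identical(gmt, list(T1 = c("g1", "g2", "g3"), T2 = c("g2", "g4")))
  writeLines("onefield", f)
  expect_error(read_gmt(f), "malformed")
})
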