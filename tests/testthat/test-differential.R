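test_that("log transform maps zeros through the pseudocount and is monotone", {
  m <- tiny_matrix(matrix(c(0, 3, 1, 7), 2, 2))
  lg <- log_transform(m, pseudocount = 1)
  expect_equal(lg[1, 1], 0)
  expect_equal(lg[2, 1], 2)
  expect_true(all(diff(log_transform(matrix(sort(runif(10)), 10, 1,
    dimnames = list(letters[1:10], "s")), 0.5)) > 0))
  expect_error(log_transform(m, pseudocount = 0), "pseudocount")
})

test_that("prior moment matching recovers known hierarchical parameters", {
  set.seed(101)
  d <- 4
  sigma2 <- 4 / rchisq(5000, 4)           # d0 = 4, s0^2 = 1
  s2 <- sigma2 * rchisq(5000, d) / d
  pr <- fit_prior(s2, d)
  expect_lt(abs(pr$d0 - 4), 1)
  expect_lt(abs(pr$s02 - 1), 0.1)
  # agrees with an independent empirical-Bayes shrinkage fit
  if (requireNamespace("limma", quietly = TRUE)) {
    sq <- limma::squeezeVar(s2, df = d)
    expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
    expect_equal(pr$s02, sq$var.prior, tolerance = 1e-6)
  }
  # s0^2 within the observed variance range for finite d0
  expect_gte(pr$s02, min(s2))
  expect_lte(pr$s02, max(s2))

  # identical variances take the d0 = infinity branch
  pr_inf <- fit_prior(rep(2, 100), 4)
  expect_true(is.infinite(pr_inf$d0))

  expect_error(fit_prior(rep(0, 100), 4), "zero")
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t-test", {
  set.seed(102)
  x <- matrix(rnorm(100 * 6, sd = rep(sqrt(4 / rchisq(100, 4)), 6)), 100, 6,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("s%d", 1:6)))
  meta <- tiny_meta(c(0, 3), 3)
  colnames(x) <- meta$sample_id
  res <- moderated_t_test(x, meta, 0, 3, prior = "none")
  ref <- apply(x, 1, function(r) {
    tt <- t.test(r[4:6], r[1:3], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_lt(max(abs(res$t - ref[1, ])), 1e-8)
  expect_lt(max(abs(res$p - ref[2, ])), 1e-8)
  expect_equal(res$logFC, unname(rowMeans(x[, 4:6]) - rowMeans(x[, 1:3])))
})

test_that("degenerate proteins and shrinkage limits behave as documented", {
  meta <- tiny_meta(c(0, 3), 3)
  x <- matrix(c(rep(1, 6), c(1, 1, 1, 5, 5, 5)), 2, 6, byrow = TRUE,
              dimnames = list(c("flat", "shift"), meta$sample_id))
  pr <- structure(list(d0 = 4, s02 = 0.5), class = "ebayes_prior")
  res <- moderated_t_test(x, meta, 0, 3, prior = pr)
  expect_equal(res$logFC[1], 0)
  expect_equal(res$p[1], 1)
  expect_gt(res$t[2], 0)
  # d0 = Inf gives the fixed-variance statistic with normal reference
  pr_inf <- structure(list(d0 = Inf, s02 = 1), class = "ebayes_prior")
  res_inf <- moderated_t_test(x, meta, 0, 3, prior = pr_inf)
  expect_equal(res_inf$t[2], 4 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res_inf$p[2], 2 * pnorm(-4 / sqrt(2 / 3)), tolerance = 1e-12)
  # groups with < 2 samples are an error
  meta1 <- meta[-(1:2), ]
  expect_error(moderated_t_test(x[, -(1:2)], meta1, 0, 3), ">= 2 samples")
})

test_that("BH adjustment matches the hand oracle and reference implementation", {
  expect_equal(unname(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(unname(benjamini_hochberg(rep(1, 5))), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  set.seed(103)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_identical(benjamini_hochberg(p), p.adjust(p, method = "BH"))
  }
})

test_that("planted log2 shifts are detected with high sensitivity", {
  set.seed(104)
  n <- 1000; n_true <- 100
  sigma <- 0.5
  x <- matrix(rnorm(n * 6, 0, sigma), n, 6,
              dimnames = list(sprintf("P%04d", 1:n), NULL))
  x[1:n_true, 4:6] <- x[1:n_true, 4:6] + 2
  meta <- tiny_meta(c(0, 3), 3)
  colnames(x) <- meta$sample_id
  res <- moderated_t_test(x, meta, 0, 3)
  called <- res$protein[res$significant]
  sens <- mean(sprintf("P%04d", 1:n_true) %in% called)
  expect_gte(sens, 0.8)
})

test_that("volcano classes agree with brute-force thresholding", {
  set.seed(105)
  meta <- tiny_meta(c(0, 3), 3)
  x <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("P%03d", 1:200), meta$sample_id))
  x[1:40, 4:6] <- x[1:40, 4:6] + rep(runif(40, 0, 4), 3)
  res <- moderated_t_test(x, meta, 0, 3)
  vt <- volcano_table(res, p_cutoff = 0.05, lfc_cutoff = 1)
  ref <- res[match(vt$protein, res$protein), ]
  expect_identical(vt$class == "padj_lfc",
                   ref$p_adjusted < 0.05 & abs(ref$logFC) > 1)
  expect_identical(vt$class == "ns",
                   ref$p_adjusted >= 0.05 & abs(ref$logFC) <= 1)
  # boundary conventions: p = 1 gives -log10 = 0 and class ns at any cutoff
  idx <- which(ref$p_adjusted == 1 & abs(ref$logFC) <= 1)
  if (length(idx)) expect_true(all(vt$class[idx] == "ns"))
  # strict inequality at the fold-change boundary
  res2 <- res[1:2, ]
  res2$logFC <- c(1, 1.01)
  res2$p_adjusted <- c(1e-6, 1e-6)
  attr(res2, "prior") <- attr(res, "prior")
  class(res2) <- class(res)
  vt2 <- volcano_table(res2, p_cutoff = 0.05, lfc_cutoff = 1)
  expect_identical(sort(vt2$class), c("padj", "padj_lfc"))
})
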