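test_that("split-half replicates use disjoint, exhaustive feature halves", {
  d1 <- random_features(6, 4, seed = 1)
  d2 <- random_features(6, 6, seed = 2)
  rs <- split_half_resample(d1, d2, n_bs = 1, seed = 3)
  expect_identical(rs$n_bs, 1L)
  expect_length(rs$replicates[[1]]$ref_features, 2L)

  # identical seeds give identical replicate feature sets
  rs2 <- split_half_resample(d1, d2, n_bs = 5, seed = 9)
  rs3 <- split_half_resample(d1, d2, n_bs = 5, seed = 9)
  expect_identical(lapply(rs2$replicates, `[[`, "ref_features"),
                   lapply(rs3$replicates, `[[`, "ref_features"))

  expect_error(split_half_resample(d1[, 1:3], d2, 1), "4 reference features")
  bad <- d2
  rownames(bad) <- rev(rownames(bad))
  expect_error(split_half_resample(d1, bad, 1), "identical subject labels")
})

test_that("each feature lands in the reference half about half the time", {
  d1 <- random_features(5, 100, seed = 4)
  d2 <- random_features(5, 100, seed = 5)
  rs <- split_half_resample(d1, d2, n_bs = 200, seed = 6)
  counts <- table(factor(unlist(lapply(rs$replicates, `[[`, "ref_features")),
                         levels = 1:100))
  # binomial(200, 1/2): 3 sigma around 100
  expect_true(all(abs(counts - 100) <= 3 * sqrt(200 * 0.25)))
})

test_that("align_scale matches off-diagonal moments exactly", {
  y <- unclass_mat(random_simmat(7, 11))
  expect_equal(align_scale(y, y), y, tolerance = 1e-12)
  expect_equal(align_scale(2 * y + 3, y), y, tolerance = 1e-10)

  ref <- unclass_mat(random_simmat(7, 12))
  out <- align_scale(y, ref)
  off <- row(y) != col(y)
  expect_equal(mean(out[off]), mean(ref[off]), tolerance = 1e-10)
  expect_equal(stats::sd(out[off]), stats::sd(ref[off]), tolerance = 1e-10)
  expect_error(align_scale(matrix(1, 3, 3), matrix(1, 3, 3)), "degenerate")
})

test_that("empirical p-values follow the regularized counting formula", {
  expect_equal(empirical_pvalues(as.list(1:199), observed = 200), 1 / 200)
  expect_equal(empirical_pvalues(as.list(1:199), observed = 0), 1)
  # ties count as exceedances
  expect_equal(empirical_pvalues(as.list(rep(5, 99)), observed = 5), 1)
  # paired observed arrays
  p <- empirical_pvalues(list(c(1, 10), c(1, 10)), list(c(2, 2), c(0, 20)))
  expect_equal(p, c((1 + 1) / 3, (1 + 1) / 3))
  expect_error(empirical_pvalues(list(), observed = 1), "n_bs")
})

test_that("p_of_k is the exceedance proportion and non-increasing", {
  expect_equal(p_of_k(rep(5L, 10), 6), c(1, 1, 1, 1, 1, 0))
  kh <- c(1L, 2L, 2L, 4L)
  expect_equal(p_of_k(kh, 4), c(1, 0.75, 0.25, 0.25))
  expect_true(all(diff(p_of_k(sample(1:7, 50, TRUE), 7)) <= 0))
  expect_error(p_of_k(integer(0), 3), "estimates")
})

test_that("the combined p-value follows its contract", {
  expect_equal(combined_pc(1, 0.005), 0.005)
  expect_equal(combined_pc(0, 0.001), 1)
  expect_equal(combined_pc(0.7, 1), 1)
  expect_error(combined_pc(1.2, 0.5), "0, 1")
})

test_that("cross-validated complexity is reproducible and small for pure noise", {
  d2 <- random_features(30, 60, seed = 21)
  kh1 <- crossvalidate_k(d2, 15, k_max = 10, seed = 5)
  kh2 <- crossvalidate_k(d2, 15, k_max = 10, seed = 5)
  expect_identical(kh1, kh2)
  expect_lte(stats::median(kh1), 3)
})

test_that("cross-validated complexity finds planted cluster structure", {
  tp <- simulate_tree_pair(d = 50, k = 5, L = 200, sigma0 = 0.005,
                           scenario = "A", seed = 8)
  kh <- crossvalidate_k(tp$d2, 15, k_max = 12, seed = 6)
  expect_gte(stats::median(kh), 4)
})

test_that("the pipeline keeps p-values in range and is seed-reproducible", {
  tp <- simulate_tree_pair(d = 20, k = 4, L = 60, sigma0 = 0.05,
                           scenario = "null", seed = 31)
  res <- significance_pipeline(tp$d1, tp$d2, n_bs = 19, k_max = 6, seed = 7)
  expect_true(all(res$p_persist >= 1 / 20 - 1e-12 & res$p_persist <= 1))
  expect_true(all(res$p_c >= 0 & res$p_c <= 1))
  expect_true(all(diff(res$p_k) <= 0))
  expect_identical(dim(res$p_c), c(20L, 6L))

  res2 <- significance_pipeline(tp$d1, tp$d2, n_bs = 19, k_max = 6, seed = 7)
  expect_equal(res$p_c, res2$p_c)
  expect_identical(res$k_hat_samples, res2$k_hat_samples)

  expect_error(significance_pipeline(tp$d1, tp$d2, n_bs = 0, k_max = 6), "n_bs")
})

test_that("globally rescaling the target features leaves all p-values unchanged", {
  tp <- simulate_tree_pair(d = 15, k = 3, L = 40, sigma0 = 0.05,
                           scenario = "A", seed = 33)
  res1 <- significance_pipeline(tp$d1, tp$d2, n_bs = 9, k_max = 5, seed = 2)
  res2 <- significance_pipeline(tp$d1, 3.7 * tp$d2, n_bs = 9, k_max = 5, seed = 2)
  expect_equal(res1$p_c, res2$p_c, tolerance = 1e-10)
  expect_identical(res1$k_hat_samples, res2$k_hat_samples)
})

test_that("externally bootstrapped replicate matrices are accepted", {
  d1 <- random_features(10, 20, seed = 41)
  d2 <- random_features(10, 20, seed = 42)
  rs <- split_half_resample(d1, d2, n_bs = 7, seed = 1)
  ext <- resample_set(lapply(rs$replicates, `[[`, "y_ref"),
                      lapply(rs$replicates, `[[`, "y_tar"),
                      lapply(rs$replicates, `[[`, "y2"))
  res <- significance_pipeline(NULL, d2, n_bs = 7, k_max = 4, seed = 3,
                               resamples = ext)
  expect_identical(res$n_bs, 7L)
  expect_true(all(res$p_persist >= 1 / 8 - 1e-12))
})

test_that("a structural change inflates recipient-cluster significance", {
  tp <- simulate_tree_pair(d = 100, k = 10, L = 300, sigma0 = 0.05,
                           scenario = "B", beta = 0.5, r = 0.5, seed = 5)
  res <- significance_pipeline(tp$d1, tp$d2, n_bs = 29, k_max = 15, seed = 11)
  rec <- names(tp$truth$cluster)[tp$truth$cluster == tp$truth$recipient]
  rest <- setdiff(rownames(res$p_c), rec)
  mid_k <- 5:15
  sig_rate_rec <- mean(res$p_c[rec, mid_k] < 0.05)
  sig_rate_rest <- mean(res$p_c[rest, mid_k] < 0.05)
  expect_gte(sig_rate_rec, sig_rate_rest)
  expect_lt(mean(res$p_persist[rec, mid_k]), mean(res$p_persist[rest, mid_k]))
})
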