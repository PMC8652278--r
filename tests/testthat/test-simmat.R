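test_that("euclidean_dissimilarity matches geometry and the pairwise oracle", {
  # 3-4-5 triangle
  y <- euclidean_dissimilarity(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(unname(y["a", "b"]), 5)
  expect_equal(unname(diag(y)), c(0, 0))
  expect_identical(attr(y, "kind"), "dissimilarity")

  # identical rows give an all-zero matrix
  x <- matrix(1:3, 4, 3, byrow = TRUE, dimnames = list(letters[1:4], NULL))
  expect_true(all(euclidean_dissimilarity(x) == 0))

  # random case against a brute-force double loop
  set.seed(11)
  x <- matrix(rnorm(15), 5, 3, dimnames = list(letters[1:5], NULL))
  y <- euclidean_dissimilarity(x)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) oracle[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  expect_lt(max(abs(unclass(y) - oracle)), 1e-12)
})

test_that("euclidean_dissimilarity rejects missing data naming the subjects", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("sub", 1:4), NULL))
  x[2, 1] <- NA
  expect_error(euclidean_dissimilarity(x), "sub2")
})

test_that("euclidean distances satisfy the triangle inequality", {
  for (case in 1:200) {
    set.seed(case)
    x <- matrix(rnorm(6 * 3), 6, 3)
    y <- unclass(euclidean_dissimilarity(x))
    for (i in 1:6) for (j in 1:6) {
      expect_true(all(y[i, j] <= y[i, ] + y[, j] + 1e-12))
    }
  }
})

test_that("covariance_similarity matches the elementwise oracle", {
  # duplicated subject: all entries equal
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  v <- covariance_similarity(x)
  expect_true(max(abs(v - v[1, 1])) < 1e-12)

  # centred constant rows vanish
  xc <- rbind(a = rep(2, 5), b = rep(7, 5))
  expect_true(all(covariance_similarity(xc, center = TRUE) == 0))

  # random case against brute force
  set.seed(3)
  x <- matrix(rnorm(200), 4, 50, dimnames = list(letters[1:4], NULL))
  v <- covariance_similarity(x, center = TRUE, allow_negative = TRUE)
  c_i <- rowMeans(x)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- mean((x[i, ] - c_i[i]) * (x[j, ] - c_i[j]))
  }
  expect_lt(max(abs(unclass(v) - oracle)), 1e-12)

  expect_error(covariance_similarity(x[, 1, drop = FALSE]), "2 features")
  expect_error(covariance_similarity(matrix(c(1, -1, -1, 1), 2, 2)), "negative")
})

test_that("centred covariance has zero row sums for column-centred features", {
  set.seed(8)
  x <- matrix(rnorm(60), 6, 10)
  x <- sweep(x, 2, colMeans(x)) # centre each feature across subjects
  rownames(x) <- letters[1:6]
  v <- covariance_similarity(x, center = TRUE, allow_negative = TRUE)
  expect_lt(max(abs(rowSums(v))), 1e-12)
})

test_that("standardize_features drops, scales, caps and imputes as specified", {
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  x[1:5, 2] <- NA # 50% missing: dropped at the 0.4 threshold
  out <- standardize_features(x, max_missing_frac = 0.4)
  expect_false("f2" %in% colnames(out))
  expect_equal(unname(apply(out, 2, stats::sd)), rep(1, ncol(out)), tolerance = 1e-10)

  # an extreme value is clamped to cap_sd standard deviations from the mean
  z <- stats::rnorm(100)
  z <- (z - mean(z)) / stats::sd(z)
  z[1] <- 12
  xx <- cbind(f1 = z, f2 = stats::rnorm(100))
  rownames(xx) <- paste0("s", 1:100)
  capped <- standardize_features(xx, cap_sd = 10)
  zc <- capped[, "f1"]
  expect_lte(max((zc - mean(zc))), 10 * 1.0001 * stats::sd(zc))

  # already unit-variance, complete input is returned unchanged
  u <- matrix(rnorm(50), 10, 5)
  u <- sweep(u, 2, apply(u, 2, stats::sd), "/")
  dimnames(u) <- list(paste0("s", 1:10), paste0("f", 1:5))
  expect_equal(standardize_features(u), u, tolerance = 1e-10)

  expect_error(standardize_features(matrix(NA_real_, 3, 2,
    dimnames = list(letters[1:3], c("a", "b"))), max_missing_frac = 0.4),
    "dropped")
})

test_that("remove_diagonal uses the per-row extreme and keeps off-diagonals", {
  y <- similarity_matrix(matrix(c(5, 2, 2, 7), 2, 2), kind = "similarity")
  r <- remove_diagonal(y)
  expect_equal(unclass_mat(r), matrix(2, 2, 2, dimnames = dimnames(r)))
  expect_identical(attr(r, "diagonal_policy"), "next_extreme")
  # idempotent on this case
  expect_equal(unclass_mat(remove_diagonal(r)), unclass_mat(r))

  # dissimilarity: zero diagonal replaced by row minima
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3)
  yd <- euclidean_dissimilarity(x)
  rd <- remove_diagonal(yd)
  off <- unclass_mat(yd)
  diag(off) <- NA
  m_i <- apply(off, 1, min, na.rm = TRUE)
  expect_equal(unname(diag(rd)), unname(m_i))
  # off-diagonal entries never change
  expect_equal(unclass_mat(rd)[row(rd) != col(rd)],
               unclass_mat(yd)[row(yd) != col(yd)])
})

test_that("similarity_matrix enforces its invariants", {
  expect_error(similarity_matrix(matrix(1, 2, 3)), "square")
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(similarity_matrix(m), "symmetric")
  expect_error(similarity_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
  expect_error(similarity_matrix(matrix(0, 2, 2), labels = c("a", "a")), "unique")
})
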