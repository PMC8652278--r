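test_that("self-prediction reproduces the scan's own fit residuals", {
  for (s in 1:5) {
    y <- random_simmat(10, 500 + s)
    sc <- svd_scan(y, 6)
    cmp <- predict_target(sc, y)
    expect_equal(cmp$total_loss, sc$fit_loss, tolerance = 1e-8)
  }
  y <- random_simmat(12, 600)
  sc <- mixture_scan(y, 3, restarts = 1, seed = 2, max_iter = 400)
  cmp <- predict_target(sc, y)
  expect_equal(cmp$total_loss, sc$fit_loss, tolerance = 1e-6)
})

test_that("prediction is equivariant under target rescaling", {
  y <- random_simmat(9, 9)
  sc <- svd_scan(y, 9)
  for (a_mult in c(2.5, -0.7)) {
    cmp <- predict_target(sc, a_mult * unclass_mat(y))
    expect_equal(cmp$total_loss, abs(a_mult) * sc$fit_loss, tolerance = 1e-8)
  }
  # full-rank structure predicts any target exactly
  z <- random_simmat(9, 10)
  cmp <- predict_target(sc, z)
  expect_lt(cmp$total_loss[9], 1e-8)
  expect_lt(max(abs(cmp$residuals[[9]])), 1e-7)
})

test_that("persistence is the row sum of squared residuals", {
  y <- random_simmat(8, 31)
  sc <- svd_scan(y, 5)
  z <- random_simmat(8, 32)
  cmp <- predict_target(sc, z)
  for (i in seq_along(cmp$k_values)) {
    oracle <- apply(cmp$residuals[[i]]^2, 1, sum)
    expect_equal(unname(cmp$persistence[, i]), unname(oracle), tolerance = 1e-12)
    # column sums equal the squared Frobenius norm
    expect_equal(sum(cmp$persistence[, i]), cmp$total_loss[i]^2, tolerance = 1e-10)
  }
  expect_identical(persistence_matrix(cmp), cmp$persistence)
  # a single off-diagonal residual r contributes r^2 to both touched subjects
  r <- matrix(0, 4, 4)
  r[2, 3] <- r[3, 2] <- 1.5
  expect_equal(unname(rowSums(r^2)), c(0, 2.25, 2.25, 0))
})

test_that("subjects are aligned by label and disjoint labels are rejected", {
  y <- random_simmat(6, 41)
  sc <- svd_scan(y, 3)
  perm <- sample(rownames(y))
  y2 <- unclass_mat(y)[perm, perm]
  cmp <- predict_target(sc, y2)
  expect_equal(cmp$total_loss, sc$fit_loss, tolerance = 1e-8)

  bad <- y2
  dimnames(bad) <- list(paste0("x", 1:6), paste0("x", 1:6))
  expect_error(predict_target(sc, bad), "labels")
})

test_that("total loss is monotone in k even when per-subject persistence is not", {
  # a target whose clustering differs by one subject: its persistence rises
  # before the extra structure is absorbed, while the total loss cannot
  a1 <- mixture_assignment(12, 3)
  a2 <- a1
  a2[1, ] <- c(0, 1, 0) # subject 1 changes cluster in the target
  x <- diag(c(6, 4, 2)) + 0.5
  y1 <- a1 %*% x %*% t(a1)
  y2 <- a2 %*% x %*% t(a2)
  sc <- svd_scan(y1, 8)
  cmp <- predict_target(sc, y2)
  expect_true(all(diff(cmp$total_loss) <= 1e-8))
  # at least one subject's persistence is non-monotone across the scan
  nonmono <- apply(cmp$persistence, 1, function(p) any(diff(p) > 1e-10))
  expect_true(any(nonmono))
})

test_that("excess persistence contrasts a group with its complement", {
  p <- matrix(1, 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  ex <- excess_persistence(p, c("s1", "s2"))
  expect_equal(ex$excess, rep(0, 4))
  p2 <- p
  p2[1:2, ] <- p2[1:2, ] + 3
  expect_equal(excess_persistence(p2, c("s1", "s2"))$excess, rep(3, 4))
  expect_error(excess_persistence(p, character(0)), "subset")
  expect_error(excess_persistence(p, paste0("s", 1:6)), "subset")
})

test_that("group residual summaries aggregate squared residuals by cluster pair", {
  y <- random_simmat(6, 55)
  sc <- svd_scan(y, 3)
  z <- random_simmat(6, 56)
  cmp <- predict_target(sc, z)
  # singleton partition returns each squared residual entry
  singles <- as.list(rownames(y))
  names(singles) <- rownames(y)
  tab <- group_residual_summary(cmp, singles)
  k1 <- tab[tab$k == 2, ]
  r2 <- cmp$residuals[[2]]^2
  for (row in sample(nrow(k1), 10)) {
    expect_equal(k1$sum_sq[row], r2[k1$from[row], k1$to[row]], tolerance = 1e-12)
  }
  # the whole-set partition returns the squared Frobenius norm per k
  all_grp <- group_residual_summary(cmp, list(all = rownames(y)))
  expect_equal(all_grp$sum_sq, cmp$total_loss^2, tolerance = 1e-10)
  expect_error(group_residual_summary(cmp, list(a = c("s1", "s2"), b = c("s2", "s3"))),
               "overlap")
})

test_that("comparisons with a fitted diagonal exclude it from persistence", {
  set.seed(71)
  x <- random_features(12, 8, seed = 71)
  y1 <- euclidean_dissimilarity(x)
  fit <- diagonal_model_fit(y1, 3, method = "svd")
  y2 <- euclidean_dissimilarity(random_features(12, 8, seed = 72))
  cmp <- predict_target(fit, y2)
  expect_false(is.null(cmp$diagonal))
  r <- cmp$residuals[[1]]
  expect_equal(unname(cmp$persistence[, 1]), unname(rowSums(r^2)), tolerance = 1e-10)
  expect_true(all(abs(diag(r)) < 1e-12))
})
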