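test_that("coalescent trees are ultrametric, binary and seed-deterministic", {
  t1 <- coalescent_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(t1)
  expect_equal(depths[1], depths[2], tolerance = 1e-12)

  t5a <- coalescent_tree(5, seed = 7)
  t5b <- coalescent_tree(5, seed = 7)
  expect_identical(ape::write.tree(t5a), ape::write.tree(t5b))
  expect_true(ape::is.binary(t5a))
  expect_true(ape::is.ultrametric(t5a, tol = 1e-8))
  expect_true(all(t5a$edge.length > 0))
  expect_error(coalescent_tree(1), "2")
})

test_that("expected coalescent height matches 2 * (1 - 1/k)", {
  heights <- vapply(1:2000, function(s) {
    max(ape::node.depth.edgelength(coalescent_tree(10, seed = s)))
  }, numeric(1))
  # E[T_mrca] = sum_{m=2}^{10} 2 / (m (m - 1)) = 2 (1 - 1/10)
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - 1.8), 3 * se)
})

test_that("Brownian traits have the tree's covariance structure", {
  tr <- coalescent_tree(4, seed = 3)
  expect_true(all(brownian_traits(tr, 10, rate = 0, seed = 1) == 0))

  rate <- 1.5
  d0 <- brownian_traits(tr, 5000, rate = rate, seed = 2)
  v <- rate^2 * ape::vcv(tr)
  emp <- tcrossprod(d0) / ncol(d0)
  # elementwise within 3 standard errors (var of products ~ 2 v_ii v_jj / L)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt((v[i, i] * v[j, j] + v[i, j]^2) / 5000)
    expect_lt(abs(emp[i, j] - v[i, j]), 4 * se + 1e-8)
  }
  # two-tip divergence: Var(tip1 - tip2) = 2 rate^2 t for ultrametric pairs
  pair_diff <- d0[1, ] - d0[2, ]
  t_div <- stats::cophenetic(tr)[rownames(d0)[1], rownames(d0)[2]] / 2
  expect_lt(abs(stats::var(pair_diff) - 2 * rate^2 * t_div),
            4 * 2 * rate^2 * t_div * sqrt(2 / 5000))
})

test_that("subject simulation blends cluster traits with Gaussian noise", {
  a <- mixture_assignment(9, 3)
  d0 <- matrix(rnorm(3 * 20), 3, 20, dimnames = list(colnames(a), NULL))
  # sigma0 = 0 duplicates the cluster rows exactly
  d <- simulate_subjects(a, d0, sigma0 = 0, seed = 1)
  expect_equal(unname(d), unname(a %*% d0))

  # noise variance matches sigma0^2
  a1 <- matrix(1, 1, 1, dimnames = list("s1", "t1"))
  d0_1 <- matrix(0, 1, 1e4, dimnames = list("t1", NULL))
  dn <- simulate_subjects(a1, d0_1, sigma0 = 0.3, seed = 2)
  expect_lt(abs(stats::var(as.numeric(dn)) - 0.09), 3 * 0.09 * sqrt(2 / 1e4))

  # a mixed row is the midpoint of its two cluster rows
  am <- a
  am[1, ] <- c(0.5, 0.5, 0)
  dm <- simulate_subjects(am, d0, sigma0 = 0, seed = 3)
  expect_equal(unname(dm[1, ]), unname((d0[1, ] + d0[2, ]) / 2))

  expect_error(simulate_subjects(a, d0[1:2, ], 0.1), "columns")
})

test_that("scenario A rescales branches within U(0.1, 2) and keeps the topology", {
  tr <- coalescent_tree(8, seed = 5)
  t2 <- scenario_a(tr, seed = 6)
  ratios <- t2$edge.length / tr$edge.length
  expect_true(all(ratios >= 0.1 & ratios <= 2))
  expect_equal(unname(ape::dist.topo(ape::unroot(tr), ape::unroot(t2))[1]), 0)

  set.seed(7)
  draws <- stats::runif(1e4, 0.1, 2)
  expect_lt(abs(mean(draws) - 1.05), 3 * stats::sd(draws) / sqrt(1e4))
})

test_that("scenario B adds one mixture edge to part of a distant cluster pair", {
  tr <- coalescent_tree(6, seed = 9)
  a <- mixture_assignment(60, 6)
  sb <- scenario_b(tr, a, beta = 0.5, r = 0.5, seed = 10)
  rec <- attr(sb$a, "recipient")
  don <- attr(sb$a, "donor")
  affected <- attr(sb$a, "affected")
  expect_length(affected, 5L) # half of a 10-subject cluster, rounded half-up
  for (s in affected) {
    expect_equal(unname(sb$a[s, rec]), 0.5)
    expect_equal(unname(sb$a[s, don]), 0.5)
  }
  untouched <- setdiff(rownames(a), affected)
  expect_equal(sb$a[untouched, ], a[untouched, ])
  # donor at least the median patristic distance from the recipient
  dd <- stats::cophenetic(sb$tree)
  others <- setdiff(sb$tree$tip.label, rec)
  expect_gte(dd[rec, don], stats::median(dd[rec, others]))

  expect_error(scenario_b(tr, a, beta = 0, r = 0.5), "beta")
  expect_error(scenario_b(tr, a, beta = 0.5, r = 1), "r")
})

test_that("tree pairs are deterministic and exactly equal under the identity hook", {
  tp1 <- simulate_tree_pair(d = 20, k = 4, L = 50, sigma0 = 0.05,
                            scenario = "B", seed = 12)
  tp2 <- simulate_tree_pair(d = 20, k = 4, L = 50, sigma0 = 0.05,
                            scenario = "B", seed = 12)
  expect_equal(unclass_mat(tp1$y2), unclass_mat(tp2$y2))
  expect_identical(tp1$truth$recipient, tp2$truth$recipient)

  # sigma0 = 0 and unit multipliers: reference and target coincide exactly
  tp0 <- simulate_tree_pair(d = 16, k = 4, L = 30, sigma0 = 0, scenario = "A",
                            seed = 13, multipliers = rep(1, 6))
  expect_equal(unclass_mat(tp0$y1), unclass_mat(tp0$y2), tolerance = 1e-12)

  # published defaults are accepted
  tp_full <- simulate_tree_pair(seed = 14)
  expect_identical(dim(tp_full$d1), c(100L, 2000L))
  expect_identical(tp_full$truth$params$k, 10)
})

test_that("cluster sizes are as even as possible with extras at low indices", {
  a <- mixture_assignment(11, 3)
  sizes <- colSums(a)
  expect_equal(unname(sizes), c(4, 4, 3))
  expect_true(all(rowSums(a) == 1))
})
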