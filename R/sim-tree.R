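# Hierarchical mixture simulator: coalescent tree, Brownian cluster traits,
# subject-level features, and the two target scenarios.

#' Random coalescent tree over clusters
#'
#' Standard neutral coalescent on `k` tips (pairs merge uniformly at random,
#' inter-coalescence times exponential with rate `choose(m, 2)` for `m`
#' extant lineages), generated with [ape::rcoal()]. The expected tree height
#' is `2 * (1 - 1/k)`.
#'
#' @param k Number of tips (clusters), at least 2. Tips are labelled
#'   `t1..tk`.
#' @param seed Optional integer seed; the tree is deterministic given it.
#'
#' @return An ultrametric binary `phylo` tree with positive branch lengths.
#' @export
coalescent_tree <- function(k, seed = NULL) {
  check_scalar_number(k, "k", 2)
  with_seed(seed, ape::rcoal(as.integer(k)))
}

#' Brownian-motion cluster traits on a tree
#'
#' Simulates `L` independent features drifting along the tree under Brownian
#' motion from a root value of 0: increments on a branch of length `t` are
#' `Normal(0, rate^2 * t)`, so tip values have covariance `rate^2 *` (shared
#' root-to-tip path length). Implemented exactly via the Cholesky factor of
#' the tree's phylogenetic covariance matrix ([ape::vcv()]).
#'
#' @param tree A `phylo` tree.
#' @param L Number of features.
#' @param rate Brownian motion rate (standard deviation per unit branch
#'   length).
#' @param seed Optional integer seed.
#' @param innovations Optional k x L matrix of standard-normal draws to use
#'   instead of fresh ones; supplying the same innovations for two trees
#'   yields paired trait sets that differ only through the trees.
#'
#' @return A k x L matrix of tip trait values, rows named by tip label.
#' @export
brownian_traits <- function(tree, L, rate = 1, seed = NULL, innovations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  check_scalar_number(L, "L", 1)
  check_scalar_number(rate, "rate", 0)
  k <- length(tree$tip.label)
  z <- if (is.null(innovations)) {
    with_seed(seed, matrix(stats::rnorm(k * L), k, L))
  } else {
    stopifnot(identical(dim(innovations), c(k, as.integer(L))))
    innovations
  }
  if (rate == 0) {
    d0 <- matrix(0, k, L)
    rownames(d0) <- tree$tip.label
    return(d0)
  }
  v <- rate^2 * ape::vcv(tree)
  ch <- tryCatch(chol(v), error = function(e) {
    chol(v + diag(1e-10 * mean(diag(v)), k))
  })
  d0 <- t(ch) %*% z
  rownames(d0) <- rownames(v)
  d0
}

#' One-hot mixture assignment of subjects to clusters
#'
#' Subjects are assigned to the `k` clusters as evenly as possible; when `d`
#' is not a multiple of `k` the lowest-indexed clusters receive the extra
#' subjects.
#'
#' @param d Number of subjects.
#' @param k Number of clusters, named `t1..tk`.
#'
#' @return A d x k one-hot matrix with subject row names `s001, s002, ...`
#'   and a `"cluster"` attribute giving each subject's cluster label.
#' @export
mixture_assignment <- function(d, k) {
  check_scalar_number(d, "d", 1)
  check_scalar_number(k, "k", 1)
  if (d < k) stop("`d` must be at least `k`", call. = FALSE)
  sizes <- rep(floor(d / k), k)
  extra <- d - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cluster <- rep(paste0("t", seq_len(k)), times = sizes)
  a <- matrix(0, d, k,
              dimnames = list(sprintf("s%03d", seq_len(d)), paste0("t", seq_len(k))))
  a[cbind(seq_len(d), match(cluster, colnames(a)))] <- 1
  attr(a, "cluster") <- stats::setNames(cluster, rownames(a))
  a
}

#' Subject-level features from a mixture of cluster traits
#'
#' Subject i's feature l is drawn `Normal((a_i' D0)_l, sigma0^2)`: the mixture
#' row blends the cluster trait values and independent Gaussian noise is
#' added.
#'
#' @param a d x k mixture assignment (columns named by cluster / tip label).
#' @param d0 k x L cluster trait matrix (rows named by tip label).
#' @param sigma0 Feature noise standard deviation.
#' @param seed Optional integer seed.
#'
#' @return A d x L subject feature matrix.
#' @export
simulate_subjects <- function(a, d0, sigma0, seed = NULL) {
  a <- as_num_matrix(a, "a")
  d0 <- as_num_matrix(d0, "d0")
  if (ncol(a) != nrow(d0)) {
    stop("columns of `a` must match rows of `d0`", call. = FALSE)
  }
  if (!is.null(colnames(a)) && !is.null(rownames(d0))) {
    if (!setequal(colnames(a), rownames(d0))) {
      stop("cluster names of `a` and `d0` disagree", call. = FALSE)
    }
    d0 <- d0[colnames(a), , drop = FALSE]
  }
  check_scalar_number(sigma0, "sigma0", 0)
  mu <- a %*% d0
  noise <- with_seed(seed, matrix(stats::rnorm(length(mu), 0, sigma0),
                                  nrow(mu), ncol(mu)))
  out <- mu + noise
  rownames(out) <- rownames(a)
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

#' Relationship-only target tree (scenario A)
#'
#' Perturbs every branch length by an independent `Uniform(0.1, 2)`
#' multiplier, keeping the topology. This changes the relationship between
#' clusters (branch lengths, ultrametricity) but not the structure (cluster
#' membership).
#'
#' @param tree A `phylo` tree.
#' @param seed Optional integer seed.
#' @param multipliers Optional vector of branch multipliers (testing hook;
#'   length must equal the edge count).
#'
#' @return The perturbed `phylo` tree.
#' @export
scenario_a <- function(tree, seed = NULL, multipliers = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_edge <- nrow(tree$edge)
  m <- if (is.null(multipliers)) {
    with_seed(seed, stats::runif(n_edge, 0.1, 2))
  } else {
    stopifnot(length(multipliers) == n_edge)
    multipliers
  }
  tree$edge.length <- tree$edge.length * m
  tree
}

#' Structure-changing target (scenario B)
#'
#' Applies [scenario_a()] and then adds one mixture edge: a recipient tip `i`
#' is chosen uniformly, a donor tip `j` uniformly among tips at least the
#' median patristic distance from `i` (median over all other tips, ties
#' inclusive), and a fraction `r` (rounded half-up) of the subjects in cluster
#' `i` get the mixture row `(1 - beta)` on cluster `i` and `beta` on cluster
#' `j`. With `r = 0` or `r = 1` the whole cluster moves and the change
#' degenerates to a relationship change, hence the open interval requirement.
#'
#' @param tree Reference `phylo` tree.
#' @param a One-hot [mixture_assignment()].
#' @param beta Mixture proportion taken from the donor, in (0, 1).
#' @param r Fraction of recipient-cluster subjects affected, in (0, 1).
#' @param seed Optional integer seed.
#' @param multipliers Optional branch multipliers passed to [scenario_a()].
#'
#' @return List with `tree` (the perturbed tree) and `a` (the modified
#'   assignment, with attributes `recipient`, `donor`, `beta`, `r`,
#'   `affected` naming the changed subjects).
#' @export
scenario_b <- function(tree, a, beta = 0.5, r = 0.5, seed = NULL,
                       multipliers = NULL) {
  stopifnot(inherits(tree, "phylo"))
  check_scalar_number(beta, "beta")
  check_scalar_number(r, "r")
  if (beta <= 0 || beta >= 1) stop("`beta` must be in (0, 1)", call. = FALSE)
  if (r <= 0 || r >= 1) stop("`r` must be in (0, 1)", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  t2 <- scenario_a(tree, seed = seeds[1L], multipliers = multipliers)
  cluster <- attr(a, "cluster")
  a2 <- with_seed(seeds[2L], {
    dist_t <- stats::cophenetic(t2)
    tips <- t2$tip.label
    recipient <- sample(tips, 1L)
    others <- setdiff(tips, recipient)
    dists <- dist_t[recipient, others]
    eligible <- others[dists >= stats::median(dists)]
    donor <- sample(eligible, 1L)
    members <- names(cluster)[cluster == recipient]
    if (length(members) < 1L) stop("recipient cluster is empty", call. = FALSE)
    n_affected <- floor(r * length(members) + 0.5)
    affected <- sample(members, n_affected)
    out <- a
    out[affected, ] <- 0
    out[affected, recipient] <- 1 - beta
    out[affected, donor] <- beta
    attr(out, "cluster") <- cluster
    attr(out, "recipient") <- recipient
    attr(out, "donor") <- donor
    attr(out, "beta") <- beta
    attr(out, "r") <- r
    attr(out, "affected") <- affected
    out
  })
  list(tree = t2, a = a2)
}

#' Simulate a reference/target pair of tree-structured similarity matrices
#'
#' Full generative model: a coalescent tree over `k` clusters, Brownian
#' cluster traits (`L` features), subjects assigned one-hot to clusters with
#' Gaussian feature noise `sigma0`, and Euclidean distance matrices. The
#' target is generated under one of three scenarios:
#' * `"A"` - same topology, branch lengths multiplied by `U(0.1, 2)` draws,
#'   traits re-derived on the perturbed tree (a relationship change only);
#' * `"B"` - scenario A plus one mixture edge affecting a fraction `r` of a
#'   recipient cluster (a structural change);
#' * `"null"` - the identical generative model (same tree, same cluster
#'   traits), only the subject-level feature noise is redrawn.
#'
#' The Brownian innovations are drawn once and shared between the reference
#' and target trees, so scenario differences come from the trees and the
#' mixture edge, not from fresh trait noise; with all branch multipliers
#' forced to 1 and `sigma0 = 0` the pair is exactly identical.
#'
#' @param d Number of subjects (default 100).
#' @param k Number of clusters (default 10).
#' @param L Number of features (default 2000).
#' @param sigma0 Subject feature noise standard deviation (default 0.05).
#' @param scenario `"A"`, `"B"` or `"null"`.
#' @param rate Brownian motion rate (default 1).
#' @param beta,r Scenario B mixture parameters.
#' @param seed Optional integer master seed; all stages derive sub-seeds.
#' @param multipliers Optional scenario A/B branch multipliers (testing hook).
#'
#' @return List of class `"tree_pair_sim"`: `y1`, `y2`
#'   ([similarity_matrix()] dissimilarities), `d1`, `d2` (feature matrices)
#'   and `truth` (trees, assignments, cluster labels, recipient/donor
#'   metadata, parameters).
#' @export
simulate_tree_pair <- function(d = 100, k = 10, L = 2000, sigma0 = 0.05,
                               scenario = c("A", "B", "null"), rate = 1,
                               beta = 0.5, r = 0.5, seed = NULL,
                               multipliers = NULL) {
  scenario <- match.arg(scenario)
  if (d < k) stop("`d` must be at least `k`", call. = FALSE)
  seeds <- derive_seeds(seed, 5L)
  t1 <- coalescent_tree(k, seeds[1L])
  z <- with_seed(seeds[2L], matrix(stats::rnorm(k * L), k, as.integer(L)))
  a1 <- mixture_assignment(d, k)
  if (scenario == "A") {
    t2 <- scenario_a(t1, seed = seeds[3L], multipliers = multipliers)
    a2 <- a1
  } else if (scenario == "B") {
    sb <- scenario_b(t1, a1, beta = beta, r = r, seed = seeds[3L],
                     multipliers = multipliers)
    t2 <- sb$tree
    a2 <- sb$a
  } else {
    t2 <- t1
    a2 <- a1
  }
  d0_1 <- brownian_traits(t1, L, rate, innovations = z)
  d0_2 <- brownian_traits(t2, L, rate, innovations = z)
  d1 <- simulate_subjects(a1, d0_1, sigma0, seed = seeds[4L])
  d2 <- simulate_subjects(a2, d0_2, sigma0, seed = seeds[5L])
  structure(list(
    y1 = euclidean_dissimilarity(d1),
    y2 = euclidean_dissimilarity(d2),
    d1 = d1,
    d2 = d2,
    truth = list(tree1 = t1, tree2 = t2, a1 = a1, a2 = a2,
                 cluster = attr(a1, "cluster"),
                 recipient = attr(a2, "recipient"),
                 donor = attr(a2, "donor"),
                 affected = attr(a2, "affected"),
                 params = list(d = d, k = k, L = L, sigma0 = sigma0,
                               rate = rate, scenario = scenario,
                               beta = beta, r = r, seed = seed))),
    class = "tree_pair_sim")
}
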