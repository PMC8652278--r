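# Split-half resampling significance for residual persistences, cross-validated
# complexity estimation and the combined p-value.

#' Split-half resampling of feature-derived similarities
#'
#' Builds `n_bs` replicates for the resampling null. Within each replicate the
#' reference features are randomly split into two disjoint halves whose union
#' is all features (sizes `floor(L/2)` and `ceiling(L/2)` when L is odd): one
#' half yields the "sampled reference" similarity, the other the "sampled
#' target" similarity. The true target features are downsampled by the same
#' procedure (a random half) to match the noise level. Each replicate's random
#' stream is derived from `(seed, replicate index)`, so replicates are
#' reproducible and order-independent.
#'
#' @param d1 Reference subject x feature matrix.
#' @param d2 Target subject x feature matrix (same subject labels).
#' @param n_bs Number of replicates (of the order of 200 are needed to
#'   confidently reject at the 0.05 level).
#' @param builder Function turning a feature matrix into a
#'   [similarity_matrix()] (default [euclidean_dissimilarity()]).
#' @param seed Optional integer master seed.
#'
#' @return An object of class `"resample_set"`: list with `replicates` (each a
#'   list `y_ref`, `y_tar`, `y2`), `n_bs`, `seed`, `builder_name`.
#' @export
split_half_resample <- function(d1, d2, n_bs, builder = euclidean_dissimilarity,
                                seed = NULL) {
  m1 <- check_features(d1, "d1")
  m2 <- check_features(d2, "d2")
  if (!identical(rownames(m1), rownames(m2))) {
    stop("`d1` and `d2` must have identical subject labels in the same order",
         call. = FALSE)
  }
  if (ncol(m1) < 4L) stop("at least 4 reference features are required", call. = FALSE)
  check_scalar_number(n_bs, "n_bs", 1)
  n_bs <- as.integer(n_bs)
  seeds <- derive_seeds(seed, n_bs)
  half1 <- floor(ncol(m1) / 2)
  replicates <- lapply(seq_len(n_bs), function(b) {
    with_seed(seeds[b], {
      idx1 <- sample.int(ncol(m1))
      idx2 <- sample.int(ncol(m2), floor(ncol(m2) / 2))
      list(y_ref = builder(m1[, idx1[seq_len(half1)], drop = FALSE]),
           y_tar = builder(m1[, idx1[-seq_len(half1)], drop = FALSE]),
           y2 = builder(m2[, idx2, drop = FALSE]),
           ref_features = sort(idx1[seq_len(half1)]))
    })
  })
  structure(list(replicates = replicates, n_bs = n_bs, seed = seed,
                 builder_name = deparse(substitute(builder))),
            class = "resample_set")
}

#' Construct a resample set from externally bootstrapped matrices
#'
#' Entry point for data whose similarities are not computed from a simple
#' feature matrix: supply your own bootstrapped replicate matrices.
#'
#' @param y_ref,y_tar,y2 Lists (equal length) of replicate matrices: sampled
#'   reference, sampled target (both pseudo-independent resamples of the
#'   reference data) and downsampled true target.
#' @return A `"resample_set"`.
#' @export
resample_set <- function(y_ref, y_tar, y2) {
  n <- length(y_ref)
  if (length(y_tar) != n || length(y2) != n || n < 1L) {
    stop("`y_ref`, `y_tar`, `y2` must be non-empty lists of equal length",
         call. = FALSE)
  }
  replicates <- lapply(seq_len(n), function(b) {
    list(y_ref = y_ref[[b]], y_tar = y_tar[[b]], y2 = y2[[b]])
  })
  structure(list(replicates = replicates, n_bs = n, seed = NULL,
                 builder_name = "external"),
            class = "resample_set")
}

#' Align the scale of one similarity matrix to another
#'
#' Mean-centres and rescales `y` so that its off-diagonal mean and standard
#' deviation match those of `ref`:
#' `(y - mean(y)) / sd(y) * sd(ref) + mean(ref)`. Moments are computed over
#' off-diagonal entries only, because the diagonal is governed by the
#' self-similarity policy rather than by between-subject signal.
#'
#' @param y Matrix to align.
#' @param ref Reference matrix of the same shape.
#'
#' @return The aligned matrix (same class handling as the input: a plain
#'   matrix; wrap with [similarity_matrix()] if needed).
#' @export
align_scale <- function(y, ref) {
  m <- check_symmetric_input(y, "y")
  r <- check_symmetric_input(ref, "ref")
  if (!identical(dim(m), dim(r))) stop("`y` and `ref` must have the same shape", call. = FALSE)
  off <- row(m) != col(m)
  mu_y <- mean(m[off])
  sd_y <- stats::sd(m[off])
  if (!is.finite(sd_y) || sd_y == 0) {
    stop("degenerate matrix: off-diagonal standard deviation is zero", call. = FALSE)
  }
  mu_r <- mean(r[off])
  sd_r <- stats::sd(r[off])
  (m - mu_y) / sd_y * sd_r + mu_r
}

#' Regularized empirical p-values
#'
#' Elementwise `p = (1 + #\{replicates with null >= observed\}) / (1 + n_bs)`.
#' Ties count as exceedances, and the regularization keeps every p-value in
#' `[1 / (1 + n_bs), 1]`. Small p means the observed statistic exceeds the
#' resampled-reference null.
#'
#' @param null_stats List of per-replicate statistic arrays (all the same
#'   shape).
#' @param observed A single statistic array of that shape, or a list of
#'   per-replicate observed arrays (paired comparison: replicate b's null is
#'   compared against replicate b's observed).
#' @param n_bs Number of replicates (defaults to `length(null_stats)`).
#'
#' @return An array of p-values with the common shape.
#' @export
#' @examples
#' empirical_pvalues(as.list(1:199), observed = 200) # 1/200
empirical_pvalues <- function(null_stats, observed, n_bs = length(null_stats)) {
  if (n_bs < 1L) stop("`n_bs` must be at least 1", call. = FALSE)
  paired <- is.list(observed)
  if (paired && length(observed) != length(null_stats)) {
    stop("paired `observed` must have one array per replicate", call. = FALSE)
  }
  ref <- if (paired) observed[[1L]] else observed
  count <- array(0, dim = if (is.null(dim(ref))) length(ref) else dim(ref))
  for (b in seq_along(null_stats)) {
    obs_b <- if (paired) observed[[b]] else observed
    if (length(null_stats[[b]]) != length(obs_b)) {
      stop("shapes of null and observed statistics disagree", call. = FALSE)
    }
    count <- count + (null_stats[[b]] >= obs_b)
  }
  p <- (1 + count) / (1 + n_bs)
  if (!is.null(dim(ref))) {
    dim(p) <- dim(ref)
    dimnames(p) <- dimnames(ref)
  } else {
    p <- as.vector(p)
    names(p) <- names(ref)
  }
  p
}

#' @keywords internal
#' @noRd
scan_by_method <- function(y, k_max, method, restarts = 1L, seed = NULL, ...) {
  if (method == "svd") svd_scan(y, k_max)
  else mixture_scan(y, k_max, restarts = restarts, seed = seed, ...)
}

#' Cross-validated complexity estimates
#'
#' Estimates how many complexities carry reproducible signal in the target
#' data. Per replicate, the target features are split into two halves; a full
#' model (structure *and* relationship) is learned from fold 1, fold 2 is
#' aligned to fold 1 with [align_scale()], and the cross-validation error at
#' complexity k is `||fold2_aligned - A_k X1^(k) A_k'||_F`, i.e. the fold-1
#' model's prediction error on held-out data. The estimate `k_hat` is the
#' smallest k attaining the minimum error. Note the relationship is *not*
#' refit to fold 2 here - refitting would make the error non-increasing in k
#' by construction and the estimate degenerate.
#'
#' @param d2 Target subject x feature matrix (at least 4 features).
#' @param n_bs Number of replicate splits.
#' @param builder Similarity builder, as in [split_half_resample()].
#' @param method `"svd"` or `"mixture"` structure solver.
#' @param k_max Largest complexity scanned (default `min(d, 20)`).
#' @param seed Optional integer master seed.
#' @param correct_diagonal Apply [remove_diagonal()] to both fold similarities
#'   before scanning (default `TRUE`). The cross-validation error is always
#'   computed over off-diagonal entries: a truncated reconstruction cannot
#'   represent the self-similarity convention (e.g. the zero diagonal of a
#'   distance matrix), and letting the diagonal dominate the error makes the
#'   estimate degenerate at `k_max`.
#'
#' @return Integer vector of `n_bs` complexity estimates.
#' @export
crossvalidate_k <- function(d2, n_bs, builder = euclidean_dissimilarity,
                            method = c("svd", "mixture"), k_max = NULL,
                            seed = NULL, correct_diagonal = TRUE) {
  method <- match.arg(method)
  m2 <- check_features(d2, "d2")
  if (ncol(m2) < 4L) stop("at least 4 target features are required", call. = FALSE)
  check_scalar_number(n_bs, "n_bs", 1)
  n_bs <- as.integer(n_bs)
  if (is.null(k_max)) k_max <- min(nrow(m2), 20L)
  seeds <- derive_seeds(seed, n_bs)
  half <- floor(ncol(m2) / 2)
  vapply(seq_len(n_bs), function(b) {
    with_seed(seeds[b], {
      idx <- sample.int(ncol(m2))
      y1 <- builder(m2[, idx[seq_len(half)], drop = FALSE])
      y2 <- builder(m2[, idx[-seq_len(half)], drop = FALSE])
      if (correct_diagonal) {
        y1 <- remove_diagonal(y1)
        y2 <- remove_diagonal(y2)
      }
      sc <- scan_by_method(y1, k_max, method, seed = seeds[b])
      y2a <- align_scale(y2, y1)
      off <- row(y2a) != col(y2a)
      err <- vapply(seq_along(sc$k_values), function(i) {
        a <- sc$A[[i]]
        r <- y2a - a %*% sc$X[[i]] %*% t(a)
        sqrt(sum(r[off]^2))
      }, numeric(1))
      sc$k_values[which.min(err)]
    })
  }, integer(1))
}

#' Probability that complexity k describes structure
#'
#' `p_k(k)` is the proportion of replicate complexity estimates at least as
#' large as k: `p(k) = (1 / n_bs) * sum_i I(k_hat_i >= k)`. It is
#' non-increasing in k and `p_k(1) = 1` since every estimate is at least 1.
#'
#' @param k_hat_samples Integer vector of replicate estimates from
#'   [crossvalidate_k()].
#' @param k_max Length of the returned vector.
#'
#' @return Numeric vector `p_k` of length `k_max`.
#' @export
p_of_k <- function(k_hat_samples, k_max) {
  if (length(k_hat_samples) < 1L) stop("no complexity estimates supplied", call. = FALSE)
  vapply(seq_len(k_max), function(k) mean(k_hat_samples >= k), numeric(1))
}

#' Combined structural-difference p-value
#'
#' Combines the persistence p-value `p_f` with the probability `p_k` that the
#' complexity describes reproducible structure:
#' `p_c = 1 - p_k * (1 - p_f)`. `p_c` is close to 0 only if both `p_k` is
#' close to 1 (the complexity carries structure) and `p_f` is close to 0 (the
#' observed persistence exceeds the resampling null). If `p_k = 0` the
#' complexity describes no structure and `p_c = 1` regardless of `p_f`.
#'
#' @param p_k Probability in \[0, 1\] that complexity k describes structure.
#' @param p_f Empirical persistence p-value in \[0, 1\].
#'
#' @return `1 - p_k * (1 - p_f)`, vectorized.
#' @export
combined_pc <- function(p_k, p_f) {
  if (any(p_k < 0 | p_k > 1, na.rm = TRUE) || any(p_f < 0 | p_f > 1, na.rm = TRUE)) {
    stop("`p_k` and `p_f` must lie in [0, 1]", call. = FALSE)
  }
  1 - p_k * (1 - p_f)
}

#' End-to-end resampling significance for a structural comparison
#'
#' Within each split-half replicate the sampled-reference similarity is
#' scanned, and two targets are predicted from that same scan after scale
#' alignment: the sampled target (the other half of the reference features -
#' the null) and the downsampled true target (the observed). The persistence
#' p-value of cell (i, k) counts replicates whose null persistence is at least
#' the observed persistence. Complexity estimates from [crossvalidate_k()] on
#' the target give `p_k`, and the combined p-value is
#' `p_c[i, k] = 1 - p_k[k] * (1 - p_persist[i, k])`.
#'
#' No multiple-testing correction is applied: cells are strongly correlated
#' and the p-values are meant to flag which subjects drive a difference, not
#' to test for the presence of any difference. A more powerful global test
#' statistic (the Frobenius norm of the whole residual matrix) is returned as
#' `p_global` per k.
#'
#' @param d1,d2 Reference and target subject x feature matrices with matched
#'   labels.
#' @param n_bs Number of replicates (>= 1; of the order of 200 recommended).
#' @param builder Similarity builder function.
#' @param method Structure solver, `"svd"` (default) or `"mixture"`.
#' @param k_max Largest complexity (default `min(d - 1, 20)`).
#' @param seed Optional integer master seed.
#' @param resamples Optional precomputed [`resample_set`][resample_set]
#'   (external bootstrap); when given, `d1` may be `NULL` and only `d2` is
#'   used (for the complexity cross-validation).
#' @param correct_diagonal Apply [remove_diagonal()] to every replicate
#'   similarity before scanning and predicting (default `TRUE`), mirroring
#'   the recommended self-similarity correction.
#'
#' @return An object of class `"structure_significance"`: `p_persist` (d x
#'   k_max), `p_global` (length k_max), `k_hat_samples`, `p_k`, `p_c`,
#'   `k_values`, `n_bs`, `seed`, and `direction` documenting the p-value
#'   convention (`"null_geq_observed"`: small p = significant).
#' @export
significance_pipeline <- function(d1, d2, n_bs,
                                  builder = euclidean_dissimilarity,
                                  method = c("svd", "mixture"),
                                  k_max = NULL, seed = NULL,
                                  resamples = NULL, correct_diagonal = TRUE) {
  method <- match.arg(method)
  m2 <- check_features(d2, "d2")
  if (is.null(k_max)) k_max <- min(nrow(m2) - 1L, 20L)
  seeds <- derive_seeds(seed, 2L)
  rs <- if (is.null(resamples)) {
    split_half_resample(d1, d2, n_bs, builder, seed = seeds[1L])
  } else {
    stopifnot(inherits(resamples, "resample_set"))
    resamples
  }
  n_bs <- rs$n_bs
  null_P <- vector("list", n_bs)
  obs_P <- vector("list", n_bs)
  null_F <- vector("list", n_bs)
  obs_F <- vector("list", n_bs)
  for (b in seq_len(n_bs)) {
    rep_b <- rs$replicates[[b]]
    y_ref <- rep_b$y_ref
    y_tar <- rep_b$y_tar
    y2 <- rep_b$y2
    if (correct_diagonal) {
      y_ref <- remove_diagonal(y_ref)
      y_tar <- remove_diagonal(y_tar)
      y2 <- remove_diagonal(y2)
    }
    sc <- scan_by_method(y_ref, k_max, method, seed = seeds[1L] + b)
    cmp_null <- predict_target(sc, align_scale(y_tar, y_ref),
                               store_residuals = FALSE)
    cmp_obs <- predict_target(sc, align_scale(y2, y_ref),
                              store_residuals = FALSE)
    null_P[[b]] <- cmp_null$persistence
    obs_P[[b]] <- cmp_obs$persistence
    null_F[[b]] <- cmp_null$total_loss
    obs_F[[b]] <- cmp_obs$total_loss
  }
  p_persist <- empirical_pvalues(null_P, obs_P, n_bs)
  p_global <- empirical_pvalues(null_F, obs_F, n_bs)
  k_hat <- crossvalidate_k(m2, n_bs, builder, method, k_max = k_max,
                           seed = seeds[2L], correct_diagonal = correct_diagonal)
  p_k <- p_of_k(k_hat, k_max)
  p_c <- sweep(1 - p_persist, 2L, p_k, `*`)
  p_c <- 1 - p_c
  dimnames(p_c) <- dimnames(p_persist)
  structure(list(p_persist = p_persist,
                 p_global = p_global,
                 k_hat_samples = k_hat,
                 p_k = p_k,
                 p_c = p_c,
                 k_values = seq_len(k_max),
                 n_bs = n_bs,
                 seed = seed,
                 direction = "null_geq_observed"),
            class = "structure_significance")
}

#' @export
print.structure_significance <- function(x, ...) {
  cat(sprintf("<structure_significance: %d subjects, k = 1..%d, n_bs = %d>\n",
              nrow(x$p_persist), max(x$k_values), x$n_bs))
  cat(sprintf("  median k_hat = %s; cells with p_c < 0.05: %.1f%%\n",
              stats::median(x$k_hat_samples), 100 * mean(x$p_c < 0.05)))
  cat("  convention: small p = observed persistence exceeds the resampling null\n")
  invisible(x)
}
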