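# Predicting a target matrix from a reference structure scan; residuals,
# persistences and grouped residual summaries.

#' Predict a target matrix conditional on a learned structure
#'
#' For every complexity `k` in the scan, keeps the reference structure `A_k`
#' fixed and refits only the relationship to the target:
#' `X2^(k) = A_k^+ y2 (A_k^+)'` (for orthonormal SVD structures this reduces to
#' `A_k' y2 A_k`), giving the prediction `A_k X2^(k) A_k'` and the residual
#' matrix `R2^(k) = y2 - A_k X2^(k) A_k'`. The target is structurally similar
#' to the reference wherever these residuals are small: the same structure,
#' with a freely relearned relationship, explains it.
#'
#' The per-subject *residual persistence* is `P[i, k] = sum_j R2^(k)[i, j]^2`;
#' subjects whose persistence stays high across many `k` are structurally
#' anomalous in the target. If the scan carries a fitted diagonal model, a
#' target diagonal is refit by the same alternation and the persistence is
#' computed on off-diagonal residuals only (the diagonal absorbs
#' self-similarity by construction).
#'
#' @param scan A [`structure_scan`][svd_scan] learned from the reference.
#' @param y2 Target matrix ([similarity_matrix()] or plain symmetric matrix)
#'   over the same subjects. Rows/columns are reordered to match the scan's
#'   labels; disjoint label sets are an error.
#' @param store_residuals Keep the per-k d x d residual matrices (default
#'   `TRUE`; disable for large d to save memory - the persistence matrix is
#'   always computed).
#'
#' @return An object of class `"structure_comparison"`: list with `k_values`,
#'   `X2` (per-k relationships), `residuals` (per-k matrices or `NULL`),
#'   `persistence` (d x k_max), `total_loss` (per-k Frobenius norms),
#'   `diagonal` (per-k refit target diagonals or `NULL`), `labels`, `method`.
#' @export
#' @examples
#' y <- euclidean_dissimilarity(matrix(rnorm(40), 8, 5))
#' sc <- svd_scan(y, 4)
#' cmp <- predict_target(sc, y) # self-prediction: residuals = fit residuals
predict_target <- function(scan, y2, store_residuals = TRUE) {
  stopifnot(inherits(scan, "structure_scan"))
  m <- check_symmetric_input(y2, "y2")
  if (!setequal(rownames(m), scan$labels)) {
    missing_in_y2 <- setdiff(scan$labels, rownames(m))
    extra_in_y2 <- setdiff(rownames(m), scan$labels)
    stop("subject labels of `y2` do not match the scan. Missing: ",
         paste(utils::head(missing_in_y2, 5L), collapse = ", "),
         "; unexpected: ", paste(utils::head(extra_in_y2, 5L), collapse = ", "),
         call. = FALSE)
  }
  m <- m[scan$labels, scan$labels]
  d <- nrow(m)
  nk <- length(scan$k_values)
  with_diag <- !is.null(scan$diagonal)
  X2 <- vector("list", nk)
  residuals <- if (store_residuals) vector("list", nk) else NULL
  diagonal <- if (with_diag) vector("list", nk) else NULL
  persistence <- matrix(0, d, nk,
                        dimnames = list(scan$labels, paste0("k", scan$k_values)))
  total_loss <- numeric(nk)
  for (i in seq_len(nk)) {
    a <- scan$A[[i]]
    if (with_diag) {
      d2 <- rep(0, d)
      for (it in seq_len(100L)) {
        x2 <- fit_relationship(a, m - diag(d2, d))
        recon <- a %*% x2 %*% t(a)
        d2_new <- diag(m - recon)
        if (max(abs(d2_new - d2)) < 1e-10 * max(abs(m), 1)) {
          d2 <- d2_new
          break
        }
        d2 <- d2_new
      }
      r <- m - recon - diag(d2, d)
      diag(r) <- 0
      diagonal[[i]] <- d2
    } else {
      if (scan$method == "svd") {
        x2 <- crossprod(a, m) %*% a
      } else {
        x2 <- fit_relationship(a, m)
      }
      r <- m - a %*% x2 %*% t(a)
    }
    X2[[i]] <- x2
    if (store_residuals) residuals[[i]] <- r
    persistence[, i] <- rowSums(r^2)
    total_loss[i] <- frobenius(r)
  }
  structure(list(k_values = scan$k_values,
                 X2 = X2,
                 residuals = residuals,
                 persistence = persistence,
                 total_loss = total_loss,
                 diagonal = diagonal,
                 labels = scan$labels,
                 method = scan$method),
            class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("<structure_comparison: %d subjects, k = %s, method '%s'>\n",
              length(x$labels), paste(range(x$k_values), collapse = ".."),
              x$method))
  cat("total residual loss by k:\n")
  print(stats::setNames(round(x$total_loss, 4), paste0("k", x$k_values)))
  invisible(x)
}

#' Residual persistence matrix
#'
#' Returns the d x k matrix `P` with `P[i, k]` the sum over `j` of the squared
#' residual entries `R2^(k)[i, j]^2` of a comparison.
#'
#' @param c A [`structure_comparison`][predict_target].
#'
#' @return Numeric d x k matrix, subjects in rows.
#' @export
persistence_matrix <- function(c) {
  stopifnot(inherits(c, "structure_comparison"))
  c$persistence
}

#' Excess persistence of a subject group
#'
#' Mean persistence of the subjects in `group` minus the mean persistence of
#' all other subjects, at each complexity. Used to summarise whether a
#' candidate cluster (e.g. a recipient of a structural change) is worse
#' predicted than the rest of the subjects.
#'
#' @param P Persistence matrix (d x k, labelled rows) or a
#'   [`structure_comparison`][predict_target].
#' @param group Character vector of subject labels, or integer/logical row
#'   index. Must be a non-empty proper subset of the subjects.
#'
#' @return A tibble with columns `k` and `excess`.
#' @export
excess_persistence <- function(P, group) {
  if (inherits(P, "structure_comparison")) {
    ks <- P$k_values
    P <- P$persistence
  } else {
    P <- as_num_matrix(P, "P")
    ks <- seq_len(ncol(P))
  }
  idx <- if (is.character(group)) {
    if (!all(group %in% rownames(P))) {
      stop("unknown subject labels in `group`", call. = FALSE)
    }
    rownames(P) %in% group
  } else if (is.logical(group)) {
    group
  } else {
    seq_len(nrow(P)) %in% group
  }
  if (!any(idx) || all(idx)) {
    stop("`group` must be a non-empty proper subset of the subjects", call. = FALSE)
  }
  excess <- colMeans(P[idx, , drop = FALSE]) - colMeans(P[!idx, , drop = FALSE])
  tibble::tibble(k = as.integer(ks), excess = unname(excess))
}

#' Summed squared residuals between subject groups
#'
#' For a partition of the subjects into groups, sums the squared residual
#' entries over every ordered group pair at every complexity. Large
#' off-diagonal group pairs point at the pair of clusters whose mutual
#' similarity is mispredicted (e.g. a donor-recipient pair after a structural
#' mixture event).
#'
#' @param c A [`structure_comparison`][predict_target] with stored residuals.
#' @param partition Named list of character vectors of subject labels, or a
#'   factor/character vector of group ids with one entry per subject (in scan
#'   label order). Groups must be non-overlapping and cover all subjects.
#'
#' @return A tibble with columns `k`, `from`, `to`, `sum_sq`.
#' @export
group_residual_summary <- function(c, partition) {
  stopifnot(inherits(c, "structure_comparison"))
  if (is.null(c$residuals)) {
    stop("comparison was created with `store_residuals = FALSE`", call. = FALSE)
  }
  labels <- c$labels
  if (is.list(partition)) {
    memb <- rep(NA_character_, length(labels))
    names(memb) <- labels
    for (g in names(partition)) {
      hit <- partition[[g]]
      if (!all(hit %in% labels)) stop("unknown labels in partition group ", g, call. = FALSE)
      if (any(!is.na(memb[hit]))) stop("overlapping groups in `partition`", call. = FALSE)
      memb[hit] <- g
    }
    if (anyNA(memb)) stop("`partition` must cover all subjects", call. = FALSE)
  } else {
    if (length(partition) != length(labels)) {
      stop("`partition` must have one entry per subject", call. = FALSE)
    }
    memb <- as.character(partition)
    names(memb) <- labels
  }
  groups <- unique(memb)
  out <- vector("list", length(c$k_values))
  for (i in seq_along(c$k_values)) {
    r2 <- c$residuals[[i]]^2
    gg <- expand.grid(from = groups, to = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gg$sum_sq <- mapply(function(g, h) sum(r2[memb == g, memb == h]),
                        gg$from, gg$to)
    gg$k <- c$k_values[i]
    out[[i]] <- gg
  }
  tibble::as_tibble(do.call(rbind, out))[, c("k", "from", "to", "sum_sq")]
}
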