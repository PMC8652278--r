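# Construction and preprocessing of labelled (dis)similarity matrices.

#' Create a labelled (dis)similarity matrix
#'
#' A `simmat` is a square, symmetric, non-negative numeric matrix over a set of
#' uniquely labelled subjects, tagged as either a `"similarity"` (large value =
#' close) or a `"dissimilarity"` (small value = close). It is the common
#' currency of the structure-learning and comparison functions.
#'
#' Full rank is deliberately not an invariant: simulated distance matrices are
#' often numerically rank-deficient, so rank is handled lazily (with a
#' tolerance-thresholded pseudo-inverse) at decomposition time.
#'
#' @param values Square numeric matrix (or data frame). Row names are used as
#'   subject labels when `labels` is not given.
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param labels Optional character vector of unique subject labels.
#' @param diagonal_policy How the diagonal has been treated: `"raw"`,
#'   `"next_extreme"` (see [remove_diagonal()]) or `"fitted"` (diagonal model).
#' @param allow_negative Permit negative entries (e.g. a centred covariance).
#'   The relaxation is recorded in the object's metadata.
#'
#' @return A matrix of class `"simmat"` with attributes `kind` and
#'   `diagonal_policy`.
#' @export
#' @examples
#' y <- similarity_matrix(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))), kind = "dissimilarity")
similarity_matrix <- function(values,
                              kind = c("similarity", "dissimilarity"),
                              labels = NULL,
                              diagonal_policy = c("raw", "next_extreme", "fitted"),
                              allow_negative = FALSE) {
  kind <- match.arg(kind)
  diagonal_policy <- match.arg(diagonal_policy)
  m <- as_num_matrix(values, "values")
  if (nrow(m) != ncol(m)) {
    stop("similarity matrix must be square, got ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (nrow(m) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (anyNA(m)) stop("similarity matrix contains missing values", call. = FALSE)
  scale <- max(abs(m), .Machine$double.xmin)
  if (max(abs(m - t(m))) > .SYM_TOL * scale) {
    stop("matrix is not symmetric to relative tolerance 1e-10", call. = FALSE)
  }
  if (!allow_negative && min(m) < 0) {
    stop("similarity matrix has negative entries; ",
         "set `allow_negative = TRUE` to permit them", call. = FALSE)
  }
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(m)))
  if (length(labels) != nrow(m) || anyDuplicated(labels)) {
    stop("subject labels must be unique and match the matrix dimension",
         call. = FALSE)
  }
  dimnames(m) <- list(labels, labels)
  structure(m,
            class = c("simmat", "matrix", "array"),
            kind = kind,
            diagonal_policy = diagonal_policy,
            allow_negative = allow_negative)
}

#' @export
print.simmat <- function(x, ...) {
  cat(sprintf("<simmat: %s, %d subjects, diagonal '%s'>\n",
              attr(x, "kind"), nrow(x), attr(x, "diagonal_policy")))
  print(unclass_simmat(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
unclass_simmat <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' @keywords internal
#' @noRd
simmat_kind <- function(x, default = "dissimilarity") {
  k <- attr(x, "kind")
  if (is.null(k)) default else k
}

#' @keywords internal
#' @noRd
check_features <- function(data, arg = "data", require_complete = TRUE) {
  m <- as_num_matrix(data, arg)
  if (nrow(m) < 2L) stop("at least 2 subjects (rows) are required", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("subject labels must be unique", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (require_complete && anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1L, any)]
    stop("missing values in features for subject(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  m
}

#' Euclidean dissimilarity between subjects
#'
#' Builds the d x d matrix of pairwise Euclidean distances between the rows of
#' a subject x feature matrix.
#'
#' @param data Numeric matrix or data frame, subjects in rows (row names are
#'   subject labels), features in columns. No missing values are permitted;
#'   impute first with [standardize_features()] if needed.
#'
#' @return A `"dissimilarity"` [similarity_matrix()] with zero diagonal.
#' @export
#' @examples
#' x <- rbind(a = c(0, 0), b = c(3, 4))
#' euclidean_dissimilarity(x) # off-diagonal 5
euclidean_dissimilarity <- function(data) {
  m <- check_features(data)
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  d <- (d + t(d)) / 2
  similarity_matrix(d, kind = "dissimilarity", labels = rownames(m))
}

#' Covariance-type similarity between subjects
#'
#' Entry (i, j) is `mean_l (x_il - c_i) * (x_jl - c_j)` where `c_i` is the
#' per-subject feature mean when `center = TRUE` and 0 otherwise. Centring is
#' off by default: it removes any mean difference between subjects from the
#' comparison and is only recommended when the mean is known a priori to be
#' uninformative.
#'
#' @inheritParams euclidean_dissimilarity
#' @param center Subtract each subject's mean across features first.
#' @param allow_negative Permit negative entries in the result. Under the
#'   non-negativity definition of a similarity matrix negative entries are an
#'   error unless explicitly allowed; the relaxation is recorded on the object.
#'
#' @return A `"similarity"` [similarity_matrix()].
#' @export
covariance_similarity <- function(data, center = FALSE, allow_negative = FALSE) {
  m <- check_features(data)
  if (ncol(m) < 2L) stop("at least 2 features are required", call. = FALSE)
  if (center) m <- m - rowMeans(m)
  v <- tcrossprod(m) / ncol(m)
  v <- (v + t(v)) / 2
  similarity_matrix(v, kind = "similarity", labels = rownames(m),
                    allow_negative = allow_negative)
}

#' Standardize a feature matrix
#'
#' Preprocessing used before building similarities from heterogeneous feature
#' panels: drop features with too much missingness, mean-impute the rest,
#' scale every feature to unit variance, and clamp extreme values.
#'
#' Feature means used for imputation are computed before any capping. Features
#' that are constant on the observed entries cannot be scaled and are dropped.
#'
#' @inheritParams euclidean_dissimilarity
#' @param max_missing_frac Features with a missing fraction at or above this
#'   threshold are dropped (default 0.4).
#' @param cap_sd Values further than this many standard deviations from the
#'   feature mean are clamped (default 10).
#' @param impute Replace missing values by the feature mean (default `TRUE`).
#'
#' @return A complete numeric matrix with the retained features.
#' @export
standardize_features <- function(data, max_missing_frac = 0.4, cap_sd = 10,
                                 impute = TRUE) {
  m <- check_features(data, require_complete = FALSE)
  check_scalar_number(max_missing_frac, "max_missing_frac", 0, 1)
  check_scalar_number(cap_sd, "cap_sd", 0)
  miss <- colMeans(is.na(m))
  keep <- miss < max_missing_frac
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("all features dropped by the missingness filter", call. = FALSE)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
  ok <- is.finite(sdv) & sdv > 0
  m <- m[, ok, drop = FALSE]
  mu <- mu[ok]
  sdv <- sdv[ok]
  if (ncol(m) == 0L) stop("all features dropped (constant on observed entries)", call. = FALSE)
  if (impute) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mu[j]
    }
  } else if (anyNA(m)) {
    stop("missing values remain and `impute = FALSE`", call. = FALSE)
  }
  z <- sweep(m, 2L, sdv, "/")
  zmu <- mu / sdv
  lo <- rep(zmu - cap_sd, each = nrow(z))
  hi <- rep(zmu + cap_sd, each = nrow(z))
  z <- pmin(pmax(z, lo), hi)
  z
}

#' Replace the diagonal by the per-row next extreme value
#'
#' Self-similarity is often not comparable to between-subject similarity (a
#' subject is trivially identical to itself). This correction answers "if we
#' removed any excess similarity unique to the subject, how similar would it be
#' to itself?" by setting each diagonal entry to the row's most extreme
#' off-diagonal value: the row maximum for a similarity, the row minimum for a
#' dissimilarity. The result is then re-symmetrized as `(M + t(M)) / 2`, which
#' preserves all off-diagonal entries.
#'
#' The extreme is taken per row (not globally) so that row scale is preserved.
#'
#' @param y A [similarity_matrix()].
#'
#' @return A `simmat` with `diagonal_policy = "next_extreme"`.
#' @export
#' @examples
#' y <- similarity_matrix(matrix(c(5, 2, 2, 7), 2, 2), kind = "similarity")
#' remove_diagonal(y) # all entries 2
remove_diagonal <- function(y) {
  if (!inherits(y, "simmat")) {
    stop("`y` must be a simmat; see similarity_matrix()", call. = FALSE)
  }
  m <- unclass_simmat(y)
  d <- nrow(m)
  if (d < 2L) stop("at least 2 subjects are required", call. = FALSE)
  off <- m
  diag(off) <- NA_real_
  extreme <- if (simmat_kind(y) == "similarity") {
    apply(off, 1L, max, na.rm = TRUE)
  } else {
    apply(off, 1L, min, na.rm = TRUE)
  }
  diag(m) <- extreme
  m <- (m + t(m)) / 2
  similarity_matrix(m, kind = simmat_kind(y), labels = rownames(m),
                    diagonal_policy = "next_extreme",
                    allow_negative = isTRUE(attr(y, "allow_negative")))
}
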