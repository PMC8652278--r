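# Internal numerical helpers shared across modules.

# Relative symmetry tolerance used by the similarity-matrix validator.
.SYM_TOL <- 1e-10

#' @keywords internal
#' @noRd
as_num_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", arg), call. = FALSE)
  }
  x
}

# Moore-Penrose pseudo-inverse with the rank tolerance used throughout:
# singular values below max(dim) * eps * sigma_max are treated as zero.
#' @keywords internal
#' @noRd
pseudo_inverse <- function(a, warn_rank = TRUE) {
  sv <- svd(a)
  tol <- max(dim(a)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (warn_rank && sum(keep) < min(dim(a))) {
    warning("rank-deficient matrix: pseudo-inverse computed with thresholded singular values",
            call. = FALSE)
  }
  if (!any(keep)) {
    return(matrix(0, ncol(a), nrow(a)))
  }
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' @keywords internal
#' @noRd
has_full_column_rank <- function(a) {
  sv <- svd(a, nu = 0, nv = 0)$d
  tol <- max(dim(a)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol) == ncol(a)
}

#' @keywords internal
#' @noRd
frobenius <- function(m) sqrt(sum(m^2))

# One integer sub-seed per logical task (replicate, restart, simulator stage),
# derived deterministically from a master seed so parallel or reordered
# execution of tasks cannot change the randomness each task sees.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(sample.int(.Machine$integer.max - 1L, n))
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", arg,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
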