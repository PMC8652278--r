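# Learning structure A_k and relationship X^(k) from a reference matrix.

#' @keywords internal
#' @noRd
new_structure_scan <- function(method, k_values, A, X, fit_loss, labels,
                               diagonal = NULL, sigma = NULL, statuses = NULL,
                               meta = list()) {
  structure(list(method = method,
                 k_values = as.integer(k_values),
                 A = A, X = X,
                 fit_loss = as.numeric(fit_loss),
                 labels = labels,
                 diagonal = diagonal,
                 sigma = sigma,
                 statuses = statuses,
                 meta = meta),
            class = "structure_scan")
}

#' @export
print.structure_scan <- function(x, ...) {
  cat(sprintf("<structure_scan: method '%s', %d subjects, k = %s%s>\n",
              x$method, length(x$labels),
              paste(range(x$k_values), collapse = ".."),
              if (!is.null(x$diagonal)) ", with fitted diagonal" else ""))
  print(tidy.structure_scan(x))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_symmetric_input <- function(y, arg = "y") {
  m <- as_num_matrix(if (inherits(y, "simmat")) unclass_simmat(y) else y, arg)
  if (nrow(m) != ncol(m)) stop(sprintf("`%s` must be square", arg), call. = FALSE)
  scale <- max(abs(m), .Machine$double.xmin)
  if (max(abs(m - t(m))) > 1e-8 * scale) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  m
}

#' Best relationship for a fixed structure
#'
#' Given a structure `a` (d x k) and a symmetric matrix `y`, returns the k x k
#' relationship `X` minimizing the Frobenius error `||y - a X a'||_F`. When `a`
#' has full column rank the minimizer is `X = a^+ y (a^+)'` with `a^+` the
#' Moore-Penrose pseudo-inverse, and the reconstruction `a X a'` equals the
#' two-sided orthogonal projection `P_a y P_a` of `y` onto the column space of
#' `a`. Rank-deficient structures are handled by a tolerance-thresholded
#' pseudo-inverse (with a warning).
#'
#' @param a Numeric d x k structure matrix.
#' @param y Symmetric d x d numeric matrix or [similarity_matrix()].
#'
#' @return A k x k numeric matrix.
#' @export
fit_relationship <- function(a, y) {
  m <- check_symmetric_input(y)
  a <- as_num_matrix(a, "a")
  if (nrow(a) != nrow(m)) stop("`a` and `y` have incompatible dimensions", call. = FALSE)
  ap <- pseudo_inverse(a)
  ap %*% m %*% t(ap)
}

#' Structure scan by truncated eigendecomposition
#'
#' Solves the unconstrained problem `min ||y1 - A_k X A_k'||_F` for every
#' complexity `k = 1..k_max`. For a symmetric matrix the singular value
#' decomposition coincides with the eigendecomposition up to signs, so the
#' solver computes a symmetric eigendecomposition, orders components by
#' decreasing `|eigenvalue|` (ties kept in original order) and fixes signs so
#' that each vector's largest-magnitude entry is positive, making the output
#' deterministic. `A_k` holds the first `k` vectors and `X^(k)` is the diagonal
#' matrix of the corresponding (signed) eigenvalues, which by the Eckart-Young
#' theorem is the best rank-k approximation; the fit loss at `k` is
#' `sqrt(sum_{j>k} sigma_j^2)`.
#'
#' @param y1 Symmetric reference matrix ([similarity_matrix()] or plain).
#' @param k_max Largest complexity to scan (at most `d`). Defaults to `d`.
#'
#' @return A `structure_scan` with `method = "svd"`; `$sigma` holds the
#'   singular values (absolute eigenvalues) of `y1`.
#' @export
#' @examples
#' v <- c(1, 2, 3)
#' y <- tcrossprod(v) # rank 1
#' svd_scan(y, k_max = 2)$fit_loss[1] # 0
svd_scan <- function(y1, k_max = NULL) {
  m <- check_symmetric_input(y1, "y1")
  d <- nrow(m)
  if (is.null(k_max)) k_max <- d
  check_scalar_number(k_max, "k_max", 1)
  k_max <- as.integer(k_max)
  if (k_max > d) stop("`k_max` cannot exceed the number of subjects (", d, ")", call. = FALSE)
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(-abs(eg$values), seq_along(eg$values))
  lambda <- eg$values[ord]
  vectors <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  rownames(vectors) <- rownames(m)
  sigma <- abs(lambda)
  tail_loss <- sqrt(rev(cumsum(rev(c(sigma[-1]^2, 0)))))
  ks <- seq_len(k_max)
  A <- lapply(ks, function(k) vectors[, seq_len(k), drop = FALSE])
  X <- lapply(ks, function(k) diag(lambda[seq_len(k)], k, k))
  new_structure_scan("svd", ks, A, X, tail_loss[ks], rownames(m),
                     sigma = sigma, meta = list(eigenvalues = lambda))
}

#' @keywords internal
#' @noRd
dirichlet_rows <- function(d, k) {
  g <- matrix(stats::rexp(d * k), d, k)
  g / rowSums(g)
}

#' @keywords internal
#' @noRd
renormalize_rows <- function(a, eps = 1e-12) {
  a[a < eps] <- eps
  a / rowSums(a)
}

#' Simplex-constrained mixture factorization at one complexity
#'
#' Fits `y1 ~ A X A'` where the rows of `A` live on the probability simplex
#' (non-negative, summing to 1) and `X` is unconstrained, by alternating
#' Lee-Seung style multiplicative updates. The `A` update multiplies
#' entrywise by `N / D` with numerator `N = y1' A X + y1 A X'` and denominator
#' `D = A X A'A X' + A X' A'A X` (a small `eps` added to the denominator);
#' rows are renormalized onto the simplex after every update. During the
#' iterations `X` is updated by the multiplicative rule with numerator
#' `A' y1 A` and denominator `A'A X A'A`, which keeps `X` in the positive
#' cone and, empirically, avoids the merged-cluster local optima that an
#' exact interleaved solve falls into. At termination the relationship is
#' polished with the exact pseudo-inverse solve of [fit_relationship()]
#' (optimal for a full-column-rank structure, so it can only lower the loss),
#' hence the reported `(A, X)` satisfies the projection identity
#' `A X A' = P_A y1 P_A`.
#'
#' Each joint step is guarded: the multiplicative ratios are raised to a step
#' exponent that grows while full steps keep succeeding and is halved until
#' the loss does not increase, so the recorded loss trace is non-increasing.
#' Iteration stops when the relative change in the Frobenius loss drops below
#' `tol` (or the loss falls below `1e-10 * ||y1||_F`), when `max_iter` is
#' reached, or when the loss has failed to improve for `patience` consecutive
#' iterations (status `"stalled"`; the best iterate is returned). Exact zeros
#' in `A` are absorbing under multiplicative updates, so initial rows are
#' drawn strictly positive from a symmetric Dirichlet(1) unless `init` is
#' supplied.
#'
#' @param y1 Symmetric non-negative matrix ([similarity_matrix()] or plain).
#' @param k Number of latent clusters (at most `d`).
#' @param init Optional d x k initial structure (rows are renormalized), or
#'   `NULL` for a seeded Dirichlet draw.
#' @param tol Relative loss-change convergence tolerance.
#' @param max_iter Maximum number of iterations.
#' @param patience Consecutive non-improving iterations tolerated before the
#'   fit stops with status `"stalled"`.
#' @param seed Optional integer seed for the initialization draw.
#'
#' @return A list of class `"mixture_fit"`: `structure` (d x k, simplex rows),
#'   `relationship` (k x k), `loss_trace`, `loss`, `status`
#'   (`"converged"`, `"max_iter"` or `"stalled"`) and `iterations`.
#' @export
mixture_fit <- function(y1, k, init = NULL, tol = 1e-8, max_iter = 5000,
                        patience = 20, seed = NULL) {
  m <- check_symmetric_input(y1, "y1")
  d <- nrow(m)
  check_scalar_number(k, "k", 1)
  k <- as.integer(k)
  if (k > d) stop("`k` cannot exceed the number of subjects", call. = FALSE)
  if (min(m) < 0) stop("mixture solver requires non-negative entries", call. = FALSE)
  eps <- 1e-12
  a <- if (is.null(init)) {
    with_seed(seed, dirichlet_rows(d, k))
  } else {
    renormalize_rows(as_num_matrix(init, "init"), eps)
  }
  if (!identical(dim(a), c(d, k))) stop("`init` must be d x k", call. = FALSE)
  x <- matrix(max(mean(m), eps), k, k) # positive start keeps the X-rule valid
  norm_m <- frobenius(m)
  loss <- frobenius(m - a %*% x %*% t(a))
  loss_trace <- numeric(max_iter + 2L)
  loss_trace[1L] <- loss
  best <- list(a = a, x = x, loss = loss)
  eta_start <- 1
  stall <- 0L
  status <- "max_iter"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ax <- a %*% x
    axt <- a %*% t(x)
    num_a <- m %*% (axt + ax) # y1' A X + y1 A X' with symmetric y1
    ata <- crossprod(a)
    den_a <- ax %*% (ata %*% t(x)) + axt %*% (ata %*% x)
    ratio_a <- pmax(num_a / (den_a + eps), eps)
    # Backtracked multiplicative step: the exponent eta grows while full
    # steps keep succeeding and is halved whenever the loss would increase,
    # so the recorded trace is non-increasing.
    prev <- loss
    eta <- eta_start
    backtracked <- FALSE
    repeat {
      a_cand <- renormalize_rows(a * ratio_a^eta, eps)
      num_x <- crossprod(a_cand, m) %*% a_cand
      ata_c <- crossprod(a_cand)
      den_x <- ata_c %*% x %*% ata_c
      x_cand <- x * pmax(num_x / (den_x + eps), eps)^eta
      loss_cand <- frobenius(m - a_cand %*% x_cand %*% t(a_cand))
      if (loss_cand <= prev * (1 + 1e-12) || eta < 1e-4) break
      eta <- eta / 2
      backtracked <- TRUE
    }
    accepted <- loss_cand <= prev * (1 + 1e-12)
    if (accepted) {
      a <- a_cand
      x <- x_cand
      loss <- min(loss_cand, prev)
      eta_start <- if (backtracked) 1 else min(eta_start * 1.25, 8)
    } else {
      eta_start <- 1 # rejected step keeps the previous iterate
    }
    loss_trace[iter + 1L] <- loss
    if (loss < best$loss - eps) {
      best <- list(a = a, x = x, loss = loss)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > patience) {
        status <- "stalled"
        break
      }
    }
    if (loss < 1e-10 * norm_m ||
        (accepted && abs(prev - loss) < tol * max(prev, eps))) {
      status <- "converged"
      break
    }
  }
  a <- best$a
  x <- best$x
  loss <- best$loss
  n_trace <- iter + 1L
  # terminal polish: with the structure fixed, the exact relationship solve
  # (Moore-Penrose; optimal for a full-column-rank structure) can only
  # decrease the loss
  if (has_full_column_rank(a)) {
    x_exact <- fit_relationship(a, m)
    loss_exact <- frobenius(m - a %*% x_exact %*% t(a))
    if (loss_exact <= loss) {
      x <- x_exact
      loss <- loss_exact
      n_trace <- n_trace + 1L
      loss_trace[n_trace] <- loss
    }
  }
  rownames(a) <- rownames(m)
  structure(list(structure = a, relationship = x,
                 loss_trace = loss_trace[seq_len(n_trace)],
                 loss = loss, status = status, iterations = iter),
            class = "mixture_fit")
}

#' Mixture structure scan over complexities
#'
#' Runs [mixture_fit()] for `k = 1..k_max`. Each complexity is attempted from
#' three kinds of starting point and the lowest-loss solution per `k` is kept:
#' a warm start (the best solution at `k - 1` with one extra column seeded at
#' the subject with the largest fit residual, floored at 1e-3 and row
#' renormalized), a clustering start (a one-hot structure from cutting an
#' average-linkage hierarchical clustering of `y1` into `k` groups, floored at
#' 1e-3), and `restarts` random Dirichlet draws. Warm starting encourages
#' nested, interpretable structures across the scan; the clustering start is
#' what makes the solver reliable on strongly hierarchical data, where random
#' starts are prone to merged-cluster local optima.
#'
#' @inheritParams mixture_fit
#' @param k_max Largest complexity to scan.
#' @param restarts Random restarts per complexity in addition to the warm start.
#' @param seed Optional integer seed; every restart derives its own stream.
#' @param ... Passed on to [mixture_fit()] (`tol`, `max_iter`, `patience`).
#'
#' @return A `structure_scan` with `method = "mixture"`; `$statuses` records
#'   each kept fit's termination reason.
#' @export
mixture_scan <- function(y1, k_max, restarts = 3, seed = NULL, ...) {
  m <- check_symmetric_input(y1, "y1")
  d <- nrow(m)
  check_scalar_number(k_max, "k_max", 1)
  k_max <- as.integer(k_max)
  if (k_max > d) stop("`k_max` cannot exceed the number of subjects", call. = FALSE)
  restarts <- as.integer(restarts)
  seeds <- matrix(derive_seeds(seed, k_max * max(restarts, 1L)),
                  nrow = k_max)
  # distances for the clustering start; similarities are flipped. For plain
  # matrices without a kind tag, a matrix whose diagonal is large relative to
  # its off-diagonal entries is treated as a similarity.
  kind <- attr(y1, "kind")
  if (is.null(kind)) {
    off <- m[row(m) != col(m)]
    kind <- if (mean(diag(m)) > mean(off)) "similarity" else "dissimilarity"
  }
  dvals <- if (kind == "similarity") max(m) - m else m
  hc <- stats::hclust(stats::as.dist(dvals), method = "average")
  A <- vector("list", k_max)
  X <- vector("list", k_max)
  losses <- numeric(k_max)
  statuses <- character(k_max)
  prev_fit <- NULL
  for (k in seq_len(k_max)) {
    cl <- stats::cutree(hc, k)
    ch <- matrix(1e-3, d, k)
    ch[cbind(seq_len(d), cl)] <- 1
    cands <- list(mixture_fit(m, k, init = renormalize_rows(ch), ...))
    if (!is.null(prev_fit)) {
      resid <- m - prev_fit$structure %*% prev_fit$relationship %*% t(prev_fit$structure)
      worst <- which.max(rowSums(resid^2))
      warm <- cbind(prev_fit$structure, 1e-3)
      warm[worst, k] <- 1
      warm <- renormalize_rows(warm)
      cands <- c(cands, list(mixture_fit(m, k, init = warm, ...)))
    }
    for (r in seq_len(restarts)) {
      cands <- c(cands, list(mixture_fit(m, k, seed = seeds[k, r], ...)))
    }
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "loss"))]]
    A[[k]] <- best$structure
    X[[k]] <- best$relationship
    losses[k] <- best$loss
    statuses[k] <- best$status
    prev_fit <- best
  }
  new_structure_scan("mixture", seq_len(k_max), A, X, losses, rownames(m),
                     statuses = statuses,
                     meta = list(restarts = restarts, seed = seed))
}

#' Structure fit with an explicit self-similarity diagonal
#'
#' Fits the model `y ~ A X A' + D` with `D` diagonal, by alternating (i) a
#' structure/relationship fit to `y - D` with the chosen solver at complexity
#' `k` and (ii) the exact update `D <- diag(y - A X A')`. The diagonal absorbs
#' subject-specific self-similarity that the low-rank part should not have to
#' explain; it is the slower alternative to [remove_diagonal()].
#'
#' @param y Symmetric matrix ([similarity_matrix()] or plain).
#' @param k Complexity of the low-rank part.
#' @param method `"svd"` or `"mixture"`.
#' @param tol Relative tolerance on the off-diagonal loss across outer
#'   iterations.
#' @param max_outer Maximum number of outer alternations; if reached the best
#'   iterate is returned with status `"max_outer"`.
#' @param ... Passed to the inner solver ([mixture_fit()] options).
#'
#' @return A `structure_scan` with a single complexity `k` and a `$diagonal`
#'   entry (list with the length-d vector `D`); `$statuses` records the outer
#'   termination reason.
#' @export
diagonal_model_fit <- function(y, k, method = c("svd", "mixture"),
                               tol = 1e-8, max_outer = 100, ...) {
  method <- match.arg(method)
  m <- check_symmetric_input(y)
  d_vec <- rep(0, nrow(m))
  best <- NULL
  status <- "max_outer"
  prev_loss <- Inf
  a <- NULL
  for (it in seq_len(max_outer)) {
    target <- m - diag(d_vec, nrow(m))
    fit <- if (method == "svd") {
      sc <- svd_scan(target, k)
      list(structure = sc$A[[k]], relationship = sc$X[[k]])
    } else {
      mf <- mixture_fit(pmax(target, 0), k, init = a, seed = it, ...)
      list(structure = mf$structure, relationship = mf$relationship)
    }
    a <- fit$structure
    recon <- a %*% fit$relationship %*% t(a)
    d_vec <- diag(m - recon)
    resid <- m - recon - diag(d_vec, nrow(m))
    loss <- frobenius(resid)
    if (is.null(best) || loss < best$loss) {
      best <- list(fit = fit, d = d_vec, loss = loss)
    }
    if (is.finite(prev_loss) && abs(prev_loss - loss) < tol * max(prev_loss, 1e-12)) {
      status <- "converged"
      break
    }
    prev_loss <- loss
  }
  new_structure_scan(method, k, list(best$fit$structure), list(best$fit$relationship),
                     best$loss, rownames(m),
                     diagonal = list(best$d), statuses = status,
                     meta = list(outer_iterations = it))
}
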