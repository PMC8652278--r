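# Reading and writing the artifacts: labelled matrices as CSV/TSV, trees as
# Newick, scans / comparisons / significance results as CSV directories with a
# JSON manifest.

#' @keywords internal
#' @noRd
sep_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Write / read a labelled matrix as CSV or TSV
#'
#' First column holds the row labels (header `subject`), remaining columns are
#' the matrix values under their column labels. Values round-trip to within
#' 1e-12 and labels exactly.
#'
#' @param m Labelled numeric matrix (or [similarity_matrix()]).
#' @param path Output file; `.tsv` extension selects tab separation.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns a labelled matrix.
#' @export
write_matrix_csv <- function(m, path) {
  m <- if (inherits(m, "simmat")) unclass_simmat(m) else as_num_matrix(m, "m")
  df <- data.frame(subject = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Read a (dis)similarity matrix from CSV/TSV
#'
#' @param path File written by [write_matrix_csv()] (square, labelled).
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param ... Passed to [similarity_matrix()] (e.g. `allow_negative`).
#' @return A [similarity_matrix()].
#' @export
read_similarity <- function(path, kind = c("similarity", "dissimilarity"), ...) {
  kind <- match.arg(kind)
  m <- read_matrix_csv(path)
  if (nrow(m) != ncol(m)) stop("matrix in '", path, "' is not square", call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels in '", path, "' disagree", call. = FALSE)
  }
  similarity_matrix(m, kind = kind, ...)
}

#' Serialize a structure scan to a directory
#'
#' One CSV per complexity for `A_k` and `X^(k)`, a CSV for a fitted diagonal
#' when present, and a JSON manifest recording the method, complexities, fit
#' losses, termination statuses and labels.
#'
#' @param scan A [`structure_scan`][svd_scan].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "structure_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(scan$k_values)) {
    k <- scan$k_values[i]
    a <- scan$A[[i]]
    colnames(a) <- paste0("c", seq_len(ncol(a)))
    write_matrix_csv(a, file.path(dir, sprintf("A_k%03d.csv", k)))
    x <- scan$X[[i]]
    dimnames(x) <- list(paste0("c", seq_len(nrow(x))), paste0("c", seq_len(ncol(x))))
    write_matrix_csv(x, file.path(dir, sprintf("X_k%03d.csv", k)))
    if (!is.null(scan$diagonal)) {
      dg <- matrix(scan$diagonal[[i]], ncol = 1,
                   dimnames = list(scan$labels, "D"))
      write_matrix_csv(dg, file.path(dir, sprintf("D_k%03d.csv", k)))
    }
  }
  manifest <- list(method = scan$method,
                   k_values = scan$k_values,
                   fit_loss = scan$fit_loss,
                   labels = scan$labels,
                   statuses = scan$statuses,
                   sigma = scan$sigma,
                   has_diagonal = !is.null(scan$diagonal))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a structure scan written by [write_scan()]
#'
#' @param dir Directory containing the scan artifacts.
#' @return A [`structure_scan`][svd_scan].
#' @export
read_scan <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ks <- as.integer(manifest$k_values)
  A <- lapply(ks, function(k) {
    a <- read_matrix_csv(file.path(dir, sprintf("A_k%03d.csv", k)))
    colnames(a) <- NULL
    a
  })
  X <- lapply(ks, function(k) {
    x <- read_matrix_csv(file.path(dir, sprintf("X_k%03d.csv", k)))
    dimnames(x) <- NULL
    x
  })
  diagonal <- if (isTRUE(manifest$has_diagonal)) {
    lapply(ks, function(k) {
      as.numeric(read_matrix_csv(file.path(dir, sprintf("D_k%03d.csv", k))))
    })
  }
  new_structure_scan(manifest$method, ks, A, X, manifest$fit_loss,
                     manifest$labels, diagonal = diagonal,
                     sigma = manifest$sigma, statuses = manifest$statuses)
}

#' Serialize a comparison to a directory
#'
#' Writes the persistence matrix and per-k total losses as CSV plus a JSON
#' manifest. Residual matrices are written only when `residuals = TRUE`.
#'
#' @param cmp A [`structure_comparison`][predict_target].
#' @param dir Output directory.
#' @param residuals Also write the per-k residual matrices.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(cmp, dir, residuals = FALSE) {
  stopifnot(inherits(cmp, "structure_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(cmp$persistence, file.path(dir, "persistence.csv"))
  loss <- matrix(cmp$total_loss, ncol = 1,
                 dimnames = list(paste0("k", cmp$k_values), "total_loss"))
  write_matrix_csv(loss, file.path(dir, "total_loss.csv"))
  if (residuals && !is.null(cmp$residuals)) {
    for (i in seq_along(cmp$k_values)) {
      write_matrix_csv(cmp$residuals[[i]],
                       file.path(dir, sprintf("residuals_k%03d.csv", cmp$k_values[i])))
    }
  }
  jsonlite::write_json(list(k_values = cmp$k_values, method = cmp$method,
                            labels = cmp$labels,
                            has_residuals = residuals && !is.null(cmp$residuals)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Serialize a significance result to a directory
#'
#' Writes `p_persist`, `p_c`, `p_k`, `p_global` and the complexity estimates
#' as CSV plus a JSON manifest that records the seed, replicate count and the
#' p-value direction convention (small p = observed persistence exceeds the
#' resampling null).
#'
#' @param res A [`structure_significance`][significance_pipeline].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_significance <- function(res, dir) {
  stopifnot(inherits(res, "structure_significance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(res$p_persist, file.path(dir, "p_persist.csv"))
  write_matrix_csv(res$p_c, file.path(dir, "p_c.csv"))
  pk <- cbind(p_k = res$p_k, p_global = res$p_global)
  rownames(pk) <- paste0("k", res$k_values)
  write_matrix_csv(pk, file.path(dir, "p_k.csv"))
  kh <- matrix(res$k_hat_samples, ncol = 1,
               dimnames = list(paste0("rep", seq_along(res$k_hat_samples)), "k_hat"))
  write_matrix_csv(kh, file.path(dir, "k_hat.csv"))
  jsonlite::write_json(list(n_bs = res$n_bs, seed = res$seed,
                            k_values = res$k_values,
                            direction = res$direction),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
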