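# broom-style tidiers.

#' Tidy a structure scan
#'
#' One row per complexity with the fit loss and termination status.
#'
#' @param x A [`structure_scan`][svd_scan].
#' @param ... Unused.
#' @return A tibble with columns `k`, `fit_loss`, `method`, `status`.
#' @method tidy structure_scan
#' @export
tidy.structure_scan <- function(x, ...) {
  tibble::tibble(
    k = x$k_values,
    fit_loss = x$fit_loss,
    method = x$method,
    status = if (is.null(x$statuses)) NA_character_ else x$statuses
  )
}

#' Glance at a structure scan
#'
#' @inheritParams tidy.structure_scan
#' @return One-row tibble: subject count, scanned range, final loss.
#' @method glance structure_scan
#' @export
glance.structure_scan <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$labels),
    k_max = max(x$k_values),
    method = x$method,
    final_fit_loss = x$fit_loss[length(x$fit_loss)],
    has_diagonal = !is.null(x$diagonal)
  )
}

#' Tidy a structure comparison
#'
#' Long persistence table: one row per subject and complexity.
#'
#' @param x A [`structure_comparison`][predict_target].
#' @param ... Unused.
#' @return A tibble with columns `subject`, `k`, `persistence`.
#' @method tidy structure_comparison
#' @export
tidy.structure_comparison <- function(x, ...) {
  tibble::tibble(
    subject = rep(x$labels, times = length(x$k_values)),
    k = rep(x$k_values, each = length(x$labels)),
    persistence = as.vector(x$persistence)
  )
}

#' Glance at a structure comparison
#'
#' @inheritParams tidy.structure_comparison
#' @return One-row tibble with the loss at the smallest and largest k.
#' @method glance structure_comparison
#' @export
glance.structure_comparison <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$labels),
    k_max = max(x$k_values),
    method = x$method,
    loss_first_k = x$total_loss[1L],
    loss_last_k = x$total_loss[length(x$total_loss)]
  )
}

#' Tidy a significance result
#'
#' One row per (subject, complexity) cell with the persistence p-value and the
#' combined p-value.
#'
#' @param x A [`structure_significance`][significance_pipeline].
#' @param ... Unused.
#' @return A tibble with columns `subject`, `k`, `p_persist`, `p_k`, `p_c`.
#' @method tidy structure_significance
#' @export
tidy.structure_significance <- function(x, ...) {
  d <- nrow(x$p_persist)
  tibble::tibble(
    subject = rep(rownames(x$p_persist), times = ncol(x$p_persist)),
    k = rep(x$k_values, each = d),
    p_persist = as.vector(x$p_persist),
    p_k = rep(x$p_k, each = d),
    p_c = as.vector(x$p_c)
  )
}

#' Glance at a significance result
#'
#' @inheritParams tidy.structure_significance
#' @return One-row tibble: replicate count, estimated complexity summary and
#'   the fraction of significant cells at 0.05.
#' @method glance structure_significance
#' @export
glance.structure_significance <- function(x, ...) {
  tibble::tibble(
    n_bs = x$n_bs,
    k_hat_median = stats::median(x$k_hat_samples),
    frac_pc_below_0.05 = mean(x$p_c < 0.05)
  )
}
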