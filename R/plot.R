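# Persistence charts.

#' Plot data behind a persistence chart
#'
#' Long-format tibble mapping each (subject, complexity) cell to the aesthetics
#' used by [render_persistence_chart()]: the fill is the persistence itself (a
#' monotone colour mapping) and cells that fail the significance threshold are
#' drawn smaller and desaturated.
#'
#' @param P Persistence matrix (d x k, labelled rows) or a
#'   [`structure_comparison`][predict_target].
#' @param pvals Optional matrix of p-values with the shape of `P`.
#' @param alpha Significance level; cells with `p >= alpha` are shrunk.
#'
#' @return Tibble with columns `subject`, `k`, `persistence`, `significant`,
#'   `cell_size`.
#' @export
persistence_plot_data <- function(P, pvals = NULL, alpha = 0.05) {
  if (inherits(P, "structure_comparison")) {
    ks <- P$k_values
    P <- P$persistence
  } else {
    P <- as_num_matrix(P, "P")
    ks <- seq_len(ncol(P))
  }
  if (!all(is.finite(P))) stop("`P` must be finite", call. = FALSE)
  if (is.null(rownames(P))) rownames(P) <- paste0("s", seq_len(nrow(P)))
  check_scalar_number(alpha, "alpha", 0, 1.000001)
  sig <- if (is.null(pvals)) {
    matrix(TRUE, nrow(P), ncol(P))
  } else {
    pvals <- as_num_matrix(pvals, "pvals")
    if (!identical(dim(pvals), dim(P))) {
      stop("`pvals` must have the same shape as `P`", call. = FALSE)
    }
    pvals < alpha
  }
  tibble::tibble(
    subject = factor(rep(rownames(P), times = ncol(P)), levels = rownames(P)),
    k = rep(as.integer(ks), each = nrow(P)),
    persistence = as.vector(P),
    significant = as.vector(sig),
    cell_size = ifelse(as.vector(sig), 1, 0.55)
  )
}

#' Render a residual-persistence chart
#'
#' Heatmap of the persistence matrix with subjects on the vertical axis and
#' model complexity on the horizontal axis. When p-values are supplied, cells
#' that are not significant at `alpha` are drawn as smaller, desaturated
#' rectangles, so the eye is drawn to large *and* significant persistences.
#' The rendering is intentionally simple: one colour map and two significance
#' size classes.
#'
#' @inheritParams persistence_plot_data
#' @param path Optional output file; the device is chosen by extension
#'   (`.png`, `.pdf`, ...). When `NULL` the ggplot object is returned instead.
#' @param width,height Device size in inches when writing to `path`.
#'
#' @return The path (invisibly) when `path` is given, otherwise a ggplot.
#' @export
render_persistence_chart <- function(P, pvals = NULL, alpha = 0.05,
                                     path = NULL, width = 7, height = 5) {
  df <- persistence_plot_data(P, pvals, alpha)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$subject)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$persistence,
                                    alpha = .data$significant,
                                    width = .data$cell_size,
                                    height = .data$cell_size)) +
    ggplot2::scale_fill_viridis_c(option = "magma", direction = -1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "complexity k", y = NULL, fill = "persistence") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (nlevels(df$subject) > 40) {
    p <- p + ggplot2::theme(axis.text.y = ggplot2::element_blank())
  }
  if (is.null(path)) {
    return(p)
  }
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' @rdname render_persistence_chart
#' @param object A [`structure_comparison`][predict_target].
#' @param ... Passed to [persistence_plot_data()] (`pvals`, `alpha`).
#' @method autoplot structure_comparison
#' @export
autoplot.structure_comparison <- function(object, ...) {
  render_persistence_chart(object, ...)
}

#' Scree-style plot of scan fit losses
#'
#' @param object A [`structure_scan`][svd_scan].
#' @param ... Unused.
#' @method autoplot structure_scan
#' @export
autoplot.structure_scan <- function(object, ...) {
  df <- tidy.structure_scan(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$fit_loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "complexity k", y = "Frobenius fit loss") +
    ggplot2::theme_minimal(base_size = 10)
}
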