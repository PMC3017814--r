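#' Plot a threshold sweep
#'
#' Two stacked panels over the threshold series: retained probe and
#' probe-set counts, and the commonly-selected gene count with the
#' cross-species correlation of tissue ratios. A flagged selected threshold
#' is marked with a vertical line.
#'
#' @param object A `crossmask_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmask_sweep <- function(object, ...) {
  x <- tidy(object)
  sel <- x$threshold[object$selected]
  long <- tidyr::pivot_longer(
    x,
    cols = c("n_probes_retained", "n_probesets_retained", "n_common",
             "pearson_r"),
    names_to = "metric", values_to = "value"
  )
  long$panel <- ifelse(long$metric %in% c("n_probes_retained",
                                          "n_probesets_retained"),
                       "retained", "sweep score")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                          y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "signal intensity threshold", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(sel) == 1) {
    p <- p + ggplot2::geom_vline(xintercept = sel, linetype = "dashed")
  }
  p
}

#' Plot a PCA overview of the samples
#'
#' First two principal components with axis labels carrying the variance
#' fractions; points are coloured by species and shaped by tissue when the
#' scores carry design columns.
#'
#' @param object A `crossmask_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmask_pca <- function(object, ...) {
  s <- object$scores
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if ("species" %in% names(s)) {
    aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2,
                        colour = .data$species)
  }
  p <- ggplot2::ggplot(s, aes)
  p <- if ("tissue" %in% names(s)) {
    p + ggplot2::geom_point(ggplot2::aes(shape = .data$tissue), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
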