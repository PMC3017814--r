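#' Tidy a threshold sweep
#'
#' @param x A `crossmask_sweep` tibble.
#' @param ... Unused.
#' @return A plain tibble of the per-threshold metrics.
#' @export
tidy.crossmask_sweep <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a threshold sweep
#'
#' @param x A `crossmask_sweep` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of thresholds, the selected threshold
#'   (`NA` if none flagged), the peak correlation and peak common-gene
#'   count.
#' @export
glance.crossmask_sweep <- function(x, ...) {
  sel <- x$threshold[x$selected]
  tibble::tibble(
    n_thresholds = nrow(x),
    selected_threshold = if (length(sel) == 1) sel else NA_real_,
    max_pearson_r = suppressWarnings(max(x$pearson_r, na.rm = TRUE)),
    max_n_common = max(x$n_common),
    n_probesets_total = attr(x, "n_probesets_total") %||% NA_integer_
  )
}

#' Tidy a differential-expression table
#'
#' @param x A `crossmask_de` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.crossmask_de <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a differential-expression table
#'
#' @param x A `crossmask_de` tibble.
#' @param ... Unused.
#' @return A one-row tibble: genes tested, genes significant, the cutoffs
#'   used, and the largest FDR among significant genes.
#' @export
glance.crossmask_de <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    p_cut = attr(x, "p_cut"),
    fold_cut = attr(x, "fold_cut"),
    max_fdr_significant = if (any(x$significant)) {
      max(x$fdr[x$significant])
    } else NA_real_
  )
}

#' Tidy a PCA overview
#'
#' @param x A `crossmask_pca` object.
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @export
tidy.crossmask_pca <- function(x, ...) x$scores

#' One-row summary of a PCA overview
#'
#' @param x A `crossmask_pca` object.
#' @param ... Unused.
#' @return A one-row tibble with the variance fractions of the first two
#'   components and the total component count.
#' @export
glance.crossmask_pca <- function(x, ...) {
  tibble::tibble(
    pc1_var_explained = x$var_explained[1],
    pc2_var_explained = if (length(x$var_explained) > 1) {
      x$var_explained[2]
    } else NA_real_,
    n_components = length(x$var_explained)
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  for (a in c("n_probesets_total", "species_csh", "species_target", "tissues",
              "p_cut", "fold_cut", "n_samples")) {
    attr(x, a) <- NULL
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
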