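#' Genes with at least a minimum fold change between two tissues
#'
#' Replicate expression values are averaged per tissue first; a gene is
#' selected when the absolute difference of its tissue means on the log2
#' scale reaches `log2(min_fold)`.
#'
#' @param expr Expression tibble (`probeset_id`, `probes_used`, sample
#'   columns) for one species.
#' @param design Design tibble covering the expression columns.
#' @param tissue_a,tissue_b Tissue labels to contrast.
#' @param min_fold Minimum fold change (linear scale), default 2.
#' @return Sorted character vector of selected probe-set IDs.
#' @export
fold_change_genes <- function(expr, design, tissue_a, tissue_b, min_fold = 2) {
  fc <- tissue_log2_ratio(expr, design, tissue_a, tissue_b)
  sort(fc$probeset_id[abs(fc$log2_ratio) >= log2(min_fold)])
}

# per-gene log2(mean_a) - log2(mean_b) ... on the log2 expression scale:
# difference of tissue means of log2 expression.
tissue_log2_ratio <- function(expr, design, tissue_a, tissue_b) {
  samples <- intersect(design$sample_id,
                       sample_columns(expr, c("probeset_id", "probes_used")))
  d <- design[design$sample_id %in% samples, , drop = FALSE]
  for (tt in c(tissue_a, tissue_b)) {
    if (!tt %in% d$tissue) {
      stop("tissue '", tt, "' absent from design for these samples")
    }
  }
  a_cols <- d$sample_id[d$tissue == tissue_a]
  b_cols <- d$sample_id[d$tissue == tissue_b]
  m <- wide_to_matrix(expr[c("probeset_id", samples)], "probeset_id")
  tibble::tibble(
    probeset_id = rownames(m),
    log2_ratio = rowMeans(m[, a_cols, drop = FALSE]) -
      rowMeans(m[, b_cols, drop = FALSE])
  )
}

#' Commonly-selected genes and their cross-species ratio correlation
#'
#' Intersects the fold-change gene sets of the target species and the
#' masked CSH species, and computes the Pearson correlation of the two
#' species' per-gene log2 tissue ratios over that intersection — the two
#' axes of the threshold sweep (sensitivity and accuracy).
#'
#' @param expr_target,expr_csh Expression tibbles for the two species
#'   (shared probe-set ID space).
#' @param design Design tibble covering both species' samples.
#' @param tissue_a,tissue_b Tissue labels to contrast.
#' @param min_fold Minimum fold change, default 2.
#' @return A list with `genes` (sorted IDs), `pearson_r` (`NA` when fewer
#'   than 3 common genes) and `ratios`, a tibble of the per-gene log2 ratios
#'   in each species over the common set.
#' @export
commonly_selected <- function(expr_target, expr_csh, design,
                              tissue_a, tissue_b, min_fold = 2) {
  shared <- intersect(expr_target$probeset_id, expr_csh$probeset_id)
  if (length(shared) == 0) {
    stop("the two expression matrices share no probe-set IDs")
  }
  g_target <- fold_change_genes(expr_target, design, tissue_a, tissue_b, min_fold)
  g_csh <- fold_change_genes(expr_csh, design, tissue_a, tissue_b, min_fold)
  genes <- intersect(g_target, g_csh)
  rt <- tissue_log2_ratio(expr_target, design, tissue_a, tissue_b)
  rc <- tissue_log2_ratio(expr_csh, design, tissue_a, tissue_b)
  ratios <- tibble::tibble(
    probeset_id = genes,
    log2_ratio_target = rt$log2_ratio[match(genes, rt$probeset_id)],
    log2_ratio_csh = rc$log2_ratio[match(genes, rc$probeset_id)]
  )
  r <- if (length(genes) >= 3) {
    cor(ratios$log2_ratio_target, ratios$log2_ratio_csh)
  } else {
    NA_real_
  }
  list(genes = genes, pearson_r = r, ratios = ratios)
}

#' Threshold sweep: score every masking threshold
#'
#' The optimization loop of the masking method. The target species' data is
#' preprocessed and summarized once, unmasked; the CSH species' data is
#' preprocessed once, then re-masked and re-summarized at every threshold.
#' Each threshold is scored by the retained probe/probe-set counts, the
#' number of commonly-selected differential genes, and the cross-species
#' Pearson correlation of the tissue log2 ratios over those genes.
#'
#' @param x_csh,x_target Raw linear-scale intensity tibbles for the CSH and
#'   target species (may contain MM rows; only layout PM probes are used).
#' @param layout Layout tibble.
#' @param design Design tibble covering both species.
#' @param species_csh,species_target Species labels in `design`.
#' @param thresholds Strictly increasing threshold series.
#' @param tissue_a,tissue_b Tissues contrasted for the fold-change sets.
#' @param min_fold Minimum fold change, default 2.
#' @return A `crossmask_sweep` tibble with one row per threshold and columns
#'   `threshold`, `n_probes_retained`, `n_probesets_retained`, `n_common`,
#'   `pearson_r`, `selected` (all `FALSE` until [annotate_selection()]).
#' @export
run_sweep <- function(x_csh, x_target, layout, design,
                      species_csh, species_target,
                      thresholds, tissue_a, tissue_b, min_fold = 2) {
  layout <- validate_layout(layout)
  prep <- function(x, species) {
    ids <- design$sample_id[design$species == species]
    x <- x[x$probe_id %in% layout$probe_id, c("probe_id", intersect(names(x), ids))]
    quantile_normalize(background_correct(x))
  }
  csh <- prep(x_csh, species_csh)
  target <- prep(x_target, species_target)
  expr_target <- summarize_rma(target, layout)
  rows <- purrr::map(thresholds, function(t) {
    mask <- build_mask(csh, layout, design, species_csh, t)
    counts <- retained_counts(mask, layout)
    expr_csh <- summarize_rma(csh, layout, mask)
    cs <- commonly_selected(expr_target, expr_csh, design,
                            tissue_a, tissue_b, min_fold)
    tibble::tibble(
      threshold = t,
      n_probes_retained = counts$n_probes_retained,
      n_probesets_retained = counts$n_probesets_retained,
      n_common = length(cs$genes),
      pearson_r = cs$pearson_r
    )
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- FALSE
  structure(out,
            class = c("crossmask_sweep", class(out)),
            n_probesets_total = length(unique(layout$probeset_id)),
            species_csh = species_csh,
            species_target = species_target,
            tissues = c(tissue_a, tissue_b))
}

#' Select the operating threshold from a sweep
#'
#' The default rule (`"max_correlation"`) picks the threshold with the
#' highest cross-species Pearson correlation among thresholds that retain at
#' least `min_fraction` of the chip's probe sets; ties go to the larger
#' number of commonly-selected genes, then to the smaller threshold. The
#' alternative rule (`"max_common"`) maximizes the commonly-selected gene
#' count without the retention constraint. Selection is reported, not
#' silently applied — use [annotate_selection()] to flag the chosen row.
#'
#' @param sweep A `crossmask_sweep` tibble.
#' @param rule `"max_correlation"` (default) or `"max_common"`.
#' @param min_fraction Minimum fraction of probe sets that must remain
#'   (default 0.95), relative to the chip's probe-set count.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(sweep, rule = c("max_correlation", "max_common"),
                             min_fraction = 0.95) {
  rule <- match.arg(rule)
  if (nrow(sweep) == 0) stop("empty sweep")
  total <- attr(sweep, "n_probesets_total")
  if (is.null(total)) total <- max(sweep$n_probesets_retained)
  cand <- tibble::as_tibble(sweep)
  if (rule == "max_correlation") {
    cand <- cand[cand$n_probesets_retained >= min_fraction * total &
                   !is.na(cand$pearson_r), , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("no threshold retains ", min_fraction,
           " of probe sets with a defined correlation; ",
           "consider relaxing min_fraction")
    }
    cand <- cand[order(-cand$pearson_r, -cand$n_common, cand$threshold), ]
  } else {
    cand <- cand[order(-cand$n_common, -cand$pearson_r, cand$threshold), ]
  }
  cand$threshold[1]
}

#' Flag the selected threshold row of a sweep
#'
#' @param sweep A `crossmask_sweep` tibble.
#' @param threshold The chosen threshold; must match exactly one row.
#' @return The sweep with exactly one `selected = TRUE` row.
#' @export
annotate_selection <- function(sweep, threshold) {
  hit <- sweep$threshold == threshold
  if (sum(hit) != 1L) {
    stop("threshold ", threshold, " matches ", sum(hit), " sweep rows")
  }
  sweep$selected <- hit
  sweep
}
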