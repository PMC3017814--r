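#' One-way ANOVA differential expression across tissues
#'
#' Per probe set, a fixed-effects one-way ANOVA of log2 expression across
#' tissues (computed row-wise in closed form, as array packages do), with
#' Benjamini-Hochberg FDR over the tested probe sets and all pairwise
#' tissue log2 mean differences. A gene is significant when its ANOVA
#' p-value is below `p_cut` and at least one tissue pair shows a
#' `fold_cut`-fold difference. Probe sets whose layout organism tag is in
#' `exclude_organisms` (pathogen controls on the chip) are removed before
#' testing.
#'
#' @param expr Expression tibble for one species (`probeset_id`,
#'   `probes_used`, sample columns).
#' @param design Design tibble covering the expression columns; at least 2
#'   tissues with at least 2 replicates each.
#' @param p_cut ANOVA p-value cutoff, default 1e-4.
#' @param fold_cut Pairwise fold-change cutoff (linear), default 2.
#' @param layout Optional layout tibble with an `organism` column, used for
#'   the organism exclusion.
#' @param exclude_organisms Organism tags to drop, default the pathogen
#'   control probe sets (Phytophthora sojae, Heterodera glycines).
#' @return A `crossmask_de` tibble: `probeset_id`, `f_statistic`, `p_value`,
#'   `fdr`, one `log2fc_<a>_vs_<b>` column per tissue pair,
#'   `max_abs_log2fc`, `significant`.
#' @export
anova_de <- function(expr, design, p_cut = 1e-4, fold_cut = 2, layout = NULL,
                     exclude_organisms = c("Phytophthora sojae",
                                           "Heterodera glycines")) {
  samples <- intersect(design$sample_id,
                       sample_columns(expr, c("probeset_id", "probes_used")))
  d <- design[design$sample_id %in% samples, , drop = FALSE]
  reps <- table(d$tissue)
  if (length(reps) < 2) stop("need at least 2 tissues for ANOVA")
  if (any(reps < 2)) {
    stop("tissue(s) with fewer than 2 replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  }
  if (!is.null(layout) && "organism" %in% names(layout)) {
    drop_sets <- unique(layout$probeset_id[layout$organism %in% exclude_organisms])
    expr <- expr[!expr$probeset_id %in% drop_sets, , drop = FALSE]
  }
  m <- wide_to_matrix(expr[c("probeset_id", samples)], "probeset_id")
  tissues <- sort(unique(d$tissue))
  k <- length(tissues)
  n <- ncol(m)
  groups <- lapply(tissues, function(tt) d$sample_id[d$tissue == tt])
  gm <- matrix(unlist(lapply(groups, function(g) {
    rowMeans(m[, g, drop = FALSE])
  })), nrow = nrow(m), ncol = k, dimnames = list(rownames(m), tissues))
  nj <- vapply(groups, length, 0L)
  grand <- as.vector(gm %*% nj) / n
  ssb <- as.vector((gm - grand)^2 %*% nj)
  ssw <- rowSums((m - gm[, d$tissue[match(colnames(m), d$sample_id)]])^2)
  f <- unname((ssb / (k - 1)) / (ssw / (n - k)))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  pairs <- utils::combn(tissues, 2, simplify = FALSE)
  fc <- lapply(pairs, function(pr) unname(gm[, pr[1]] - gm[, pr[2]]))
  names(fc) <- vapply(pairs, function(pr) {
    paste0("log2fc_", pr[1], "_vs_", pr[2])
  }, "")
  out <- tibble::tibble(
    probeset_id = rownames(m),
    f_statistic = f,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    !!!fc
  )
  out$max_abs_log2fc <- do.call(pmax, lapply(fc, abs))
  out$significant <- !is.na(out$p_value) & out$p_value < p_cut &
    out$max_abs_log2fc >= log2(fold_cut)
  structure(out,
            class = c("crossmask_de", class(out)),
            p_cut = p_cut, fold_cut = fold_cut,
            tissues = tissues, n_samples = n)
}

#' Principal component overview of the samples
#'
#' Samples are the observations and probe sets the variables; probe-set
#' columns are centered (not scaled) and decomposed by SVD. Variance-
#' explained fractions are reported over all components and sum to one.
#' Component signs follow the convention that the largest-magnitude loading
#' of each component is positive.
#'
#' @param expr Expression tibble (`probeset_id`, `probes_used`, sample
#'   columns) — typically both species joined over shared probe sets.
#' @param design Optional design tibble; if given, species/tissue/replicate
#'   are joined onto the scores for plotting.
#' @param n_components Number of score columns returned, default 2.
#' @return A `crossmask_pca` list: `scores` (tibble `sample_id`, `PC1`, ...,
#'   plus design columns), `var_explained` (full-length numeric), `sdev`.
#' @export
pca_overview <- function(expr, design = NULL, n_components = 2) {
  samples <- sample_columns(expr, c("probeset_id", "probes_used"))
  if (length(samples) < 2) stop("need at least 2 samples for PCA")
  m <- t(wide_to_matrix(expr[c("probeset_id", samples)], "probeset_id"))
  if (all(apply(m, 2, stats::sd) == 0)) {
    stop("expression matrix is constant: no variance to decompose")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$x <- sweep(pc$x, 2, flip, `*`)
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(nc), drop = FALSE])
  scores <- tibble::add_column(scores, sample_id = rownames(m), .before = 1)
  if (!is.null(design)) {
    scores <- dplyr::left_join(scores, design, by = "sample_id")
  }
  structure(list(scores = scores, var_explained = ve, sdev = pc$sdev,
                 loadings = pc$rotation[, seq_len(nc), drop = FALSE]),
            class = "crossmask_pca")
}

#' @export
print.crossmask_pca <- function(x, ...) {
  cat("<crossmask_pca>", nrow(x$scores), "samples;",
      "PC1", sprintf("%.1f%%,", 100 * x$var_explained[1]),
      "PC2", sprintf("%.1f%%", 100 * x$var_explained[2]), "\n")
  invisible(x)
}

#' Classify probe sets by retained-probe count
#'
#' After masking, the number of probes a probe set retains is a proxy for
#' sequence conservation between the two species: sets retaining
#' `hi_min` or more probes (10 or 11 of 11 by default) are
#' "highly conserved", sets retaining 1 to `hyper_max` (1 or 2 by default)
#' are "hyper-variable", the rest are intermediate. Sets with every probe
#' masked are labelled `all_masked` and excluded from group statistics,
#' because total masking confounds divergence with low transcript abundance.
#'
#' @param mask A `probe_mask`.
#' @param layout Layout tibble.
#' @param hi_min Minimum retained probes for the highly-conserved group.
#' @param hyper_max Maximum retained probes for the hyper-variable group
#'   (must be `< hi_min`).
#' @return Tibble `probeset_id`, `n_probes`, `retained`, `group` (factor
#'   with levels all_masked, hyper_variable, intermediate, highly_conserved).
#' @export
classify_conservation <- function(mask, layout, hi_min = 10, hyper_max = 2) {
  if (hi_min <= hyper_max) stop("hi_min must exceed hyper_max")
  per_set <- retained_counts(mask, layout)$per_set
  per_set$group <- factor(
    dplyr::case_when(
      per_set$retained == 0 ~ "all_masked",
      per_set$retained <= hyper_max ~ "hyper_variable",
      per_set$retained >= hi_min ~ "highly_conserved",
      TRUE ~ "intermediate"
    ),
    levels = c("all_masked", "hyper_variable", "intermediate",
               "highly_conserved")
  )
  per_set
}

#' Fisher-exact over-representation of functional classes
#'
#' For each functional class, a two-sided Fisher exact test on the 2x2
#' table (in/out of class by in/out of selection) against the universe,
#' Bonferroni correction over the classes tested, and a signed z-transform
#' of the adjusted p-value: `z = qnorm(1 - bonferroni_p / 2)`, positive for
#' over-representation (observed count above expected), negative for under.
#' Classes with `|z| >= z_cut` are flagged. The reported z is uncapped;
#' capping (e.g. at the display scale -4..4) is presentation only.
#'
#' @param selection Character vector of selected probe-set IDs (a subset of
#'   `universe`).
#' @param classes Tibble with columns `probeset_id`, `class_id` (a probe
#'   set may carry several classes).
#' @param universe Character vector of all probe-set IDs under
#'   consideration.
#' @param z_cut Flagging cutoff on |z|, default 1.
#' @return Tibble `class_id`, `count_in_selection`, `count_in_universe`,
#'   `fisher_p`, `bonferroni_p`, `z_value`, `direction` (over/under),
#'   `flagged`.
#' @export
fisher_overrep <- function(selection, classes, universe, z_cut = 1) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  selection <- unique(selection)
  outside <- setdiff(selection, universe)
  if (length(outside)) {
    stop("selection contains ID(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  }
  cls <- classes[classes$probeset_id %in% universe, , drop = FALSE]
  cls <- dplyr::distinct(cls, .data$class_id, .data$probeset_id)
  N <- length(universe)
  n_sel <- length(selection)
  per_class <- split(cls$probeset_id, cls$class_id)
  n_classes <- length(per_class)
  rows <- purrr::imap(per_class, function(members, cid) {
    m_cls <- length(members)
    a <- sum(members %in% selection)
    tab <- matrix(c(a, m_cls - a, n_sel - a, N - m_cls - n_sel + a), 2)
    p <- fisher.test(tab)$p.value
    bonf <- min(1, p * n_classes)
    over <- a >= n_sel * m_cls / N
    z <- qnorm(1 - bonf / 2) * (if (over) 1 else -1)
    tibble::tibble(class_id = cid,
                   count_in_selection = a,
                   count_in_universe = m_cls,
                   fisher_p = p,
                   bonferroni_p = bonf,
                   z_value = z,
                   direction = if (over) "over" else "under")
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- abs(out$z_value) >= z_cut
  out
}
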