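#' Masking fraction P
#'
#' The fraction of a species' sample files that must sit at or below the
#' intensity threshold before a probe is masked, for a design with `Ts`
#' total samples made of `S` tissue types with `R` replicates each:
#' `P = (Ts - R + 1) / Ts`. Equivalently, a probe is retained if and only if
#' at least `R` of the `Ts` signals exceed the threshold. For 3 tissues with
#' 3 replicates (`Ts = 9`), `P = 7/9`, displayed as 0.78.
#'
#' @param Ts Total number of sample files for the species.
#' @param R Replicates per tissue type (`1 <= R <= Ts`).
#' @param S Number of tissue types; if supplied, `Ts == R * S` is checked
#'   and unbalanced designs are flagged with a warning.
#' @return The exact fraction `(Ts - R + 1) / Ts` (round to 2 decimals for
#'   display).
#' @export
mask_fraction <- function(Ts, R, S = NULL) {
  stopifnot(Ts >= 1, R >= 1, is.null(S) || S >= 1)
  if (R > Ts) stop("R (", R, ") cannot exceed Ts (", Ts, ")")
  if (!is.null(S) && Ts != R * S) {
    warning("unbalanced design: Ts (", Ts, ") != R * S (", R * S, ")")
  }
  (Ts - R + 1) / Ts
}

#' Build a probe mask at one intensity threshold
#'
#' Applies the retention rule to one species' preprocessed (background-
#' corrected, quantile-normalized) probe intensities: a probe is masked when
#' fewer than `R` of that species' `Ts` samples exceed the threshold
#' (strictly), i.e. when it sits at or below the threshold in at least a
#' fraction `P = (Ts - R + 1)/Ts` of samples. With threshold 0 and positive
#' intensities nothing is masked.
#'
#' @param x Intensity tibble (`probe_id` + sample columns) containing at
#'   least the species' samples.
#' @param layout Layout tibble; only its PM probes are considered.
#' @param design Design tibble covering the species' samples.
#' @param species Species whose samples drive the masking decision.
#' @param threshold Non-negative intensity threshold (linear scale).
#' @return A `probe_mask` carrying the threshold, species and masking
#'   fraction.
#' @export
build_mask <- function(x, layout, design, species, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  layout <- validate_layout(layout)
  ds <- design_structure(design, species)
  missing <- setdiff(ds$sample_ids, names(x))
  if (length(missing)) {
    stop("intensity matrix lacks sample(s) of species '", species, "': ",
         paste(missing, collapse = ", "))
  }
  m <- wide_to_matrix(x[c("probe_id", ds$sample_ids)], "probe_id")
  if (ncol(m) != ds$Ts) stop("sample count != Ts for species '", species, "'")
  pm <- intersect(layout$probe_id, rownames(m))
  m <- m[pm, , drop = FALSE]
  above <- rowSums(m > threshold)
  masked_ids <- rownames(m)[above < ds$R]
  probes <- layout[layout$probe_id %in% masked_ids, c("probeset_id", "probe_id")]
  probe_mask(probes,
             threshold = threshold,
             species = species,
             p_fraction = mask_fraction(ds$Ts, ds$R, ds$S),
             created_from = sprintf("build_mask(species=%s, threshold=%.10g)",
                                    species, threshold))
}

#' Build one mask per threshold
#'
#' One mask file is created per intensity point of a strictly increasing
#' threshold series. Masks are nested: the mask at a lower threshold is a
#' subset of the mask at any higher one.
#'
#' @inheritParams build_mask
#' @param thresholds Strictly increasing numeric vector of thresholds.
#' @return A named list of `probe_mask` objects (names = thresholds).
#' @export
mask_series <- function(x, layout, design, species, thresholds) {
  if (length(thresholds) == 0) stop("no thresholds supplied")
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  masks <- lapply(thresholds, function(t) {
    build_mask(x, layout, design, species, t)
  })
  names(masks) <- as.character(thresholds)
  masks
}

#' Retained-probe counts under a mask
#'
#' A probe set counts as retained if at least one of its probes survives
#' masking (the minimum number of probes needed to produce an expression
#' value is one).
#'
#' @param mask A `probe_mask`.
#' @param layout Layout tibble.
#' @return A list with `n_probes_retained`, `n_probesets_retained` and
#'   `per_set`, a tibble of `probeset_id`, `n_probes`, `retained`.
#' @export
retained_counts <- function(mask, layout) {
  layout <- validate_layout(layout)
  unknown <- setdiff(mask$probe_id, layout$probe_id)
  if (length(unknown)) {
    stop("mask names probe(s) absent from layout: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  per_set <- layout |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      retained = sum(!(.data$probe_id %in% mask$probe_id)),
      .by = "probeset_id"
    ) |>
    tibble::as_tibble()
  list(
    n_probes_retained = sum(per_set$retained),
    n_probesets_retained = sum(per_set$retained >= 1L),
    per_set = per_set
  )
}
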