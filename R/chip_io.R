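#' Read a sample design table
#'
#' The design table links each array (one hybridization) to its species,
#' tissue and replicate number. All downstream operations — masking,
#' summarization, the threshold sweep, differential expression — interpret
#' intensity columns through this table.
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `species`, `tissue`, `replicate`.
#' @return A tibble with one row per sample, in file order. The
#'   `(species, tissue, replicate)` triples must be unique.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sample_id = readr::col_character(),
                         species = readr::col_character(),
                         tissue = readr::col_character(),
                         replicate = readr::col_integer()
                       ))
  validate_design(d)
}

validate_design <- function(d) {
  needed <- c("sample_id", "species", "tissue", "replicate")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("design table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  key <- paste(d$species, d$tissue, d$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (species, tissue, replicate) triple in design: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(d$replicate < 1L)) stop("replicate numbers must be positive")
  tibble::as_tibble(d[needed])
}

#' Write a sample design table
#'
#' @param design A design tibble (see [read_design()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(validate_design(design), path)
  invisible(path)
}

#' Replicate structure of one species' samples
#'
#' Derives the sample-file count `Ts`, replicate count `R` and tissue count
#' `S` for one species from the design. For a balanced design `Ts = R * S`;
#' unbalanced designs are flagged with a warning and `R` is the minimum
#' per-tissue replicate count (the masking rule then errs toward retaining).
#'
#' @param design Design tibble.
#' @param species Species label to summarise.
#' @return A list with elements `Ts`, `R`, `S`, `sample_ids`, `balanced`.
#' @export
design_structure <- function(design, species) {
  d <- design[design$species == species, , drop = FALSE]
  if (nrow(d) == 0) stop("species '", species, "' not present in design")
  reps <- table(d$tissue)
  balanced <- length(unique(as.integer(reps))) == 1L
  if (!balanced) {
    warning("unbalanced design for species '", species,
            "': replicates per tissue = ",
            paste(names(reps), as.integer(reps), sep = ":", collapse = ", "))
  }
  list(Ts = nrow(d), R = min(as.integer(reps)), S = length(reps),
       sample_ids = d$sample_id, balanced = balanced)
}

#' Read a probe-level intensity matrix
#'
#' Intensities are linear-scale, strictly positive values as exported from
#' the scanner; one row per probe, one column per sample. Columns are
#' reordered to follow the design.
#'
#' @param path Path to a tab-delimited file whose first column (`probe_id`)
#'   holds probe identifiers and remaining columns hold one sample each.
#' @param design Design tibble (see [read_design()]), or a path to one.
#' @return A tibble with `probe_id` followed by the design's sample columns.
#' @export
read_intensities <- function(path, design) {
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    design <- read_design(design)
  }
  design <- validate_design(design)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(probe_id = readr::col_character(),
                                               .default = readr::col_double()))
  if (names(x)[1] != "probe_id") names(x)[1] <- "probe_id"
  validate_intensities(x, design)
}

validate_intensities <- function(x, design) {
  if (anyDuplicated(x$probe_id)) {
    stop("duplicate probe IDs in intensity table: ",
         paste(head(unique(x$probe_id[duplicated(x$probe_id)]), 5), collapse = ", "))
  }
  samples <- sample_columns(x, "probe_id")
  extra <- setdiff(samples, design$sample_id)
  if (length(extra)) {
    stop("sample(s) in intensity matrix absent from design: ",
         paste(extra, collapse = ", "))
  }
  keep <- intersect(design$sample_id, samples)
  if (length(keep) == 0) stop("no design samples found in intensity matrix")
  x <- x[c("probe_id", keep)]
  m <- wide_to_matrix(x, "probe_id")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing intensity for probe '", rownames(m)[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'")
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive intensity for probe '", rownames(m)[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'")
  }
  x
}

#' Write a probe-level intensity matrix
#'
#' @param x Intensity tibble (`probe_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(x, path) {
  stopifnot(names(x)[1] == "probe_id")
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a chip layout
#'
#' The layout maps each probe set to its ordered perfect-match (PM) probes,
#' optionally with paired mismatch (MM) probe IDs and an organism tag per
#' probe set (used, e.g., to exclude pathogen control probe sets from
#' differential-expression testing).
#'
#' @param path Path to a tab-delimited file with columns `probeset_id`,
#'   `probe_id`, `probe_index` and optionally `mm_probe_id`, `organism`.
#' @return A tibble ordered by probe set and `probe_index`. Within each
#'   probe set the indices must run 1..k without gaps, and no probe may
#'   belong to two probe sets.
#' @export
read_layout <- function(path) {
  l <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         probeset_id = readr::col_character(),
                         probe_id = readr::col_character(),
                         probe_index = readr::col_integer(),
                         .default = readr::col_character()
                       ))
  validate_layout(l)
}

validate_layout <- function(l) {
  needed <- c("probeset_id", "probe_id", "probe_index")
  missing <- setdiff(needed, names(l))
  if (length(missing)) {
    stop("layout lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(l$probe_id)) {
    dup <- unique(l$probe_id[duplicated(l$probe_id)])
    owners <- unique(l$probeset_id[l$probe_id %in% dup])
    stop("probe(s) assigned to more than one probe set: ",
         paste(head(dup, 5), collapse = ", "),
         " (probe sets ", paste(head(owners, 5), collapse = ", "), ")")
  }
  l <- dplyr::arrange(l, .data$probeset_id, .data$probe_index)
  bad <- l |>
    dplyr::summarise(ok = all(.data$probe_index == seq_len(dplyr::n())),
                     .by = "probeset_id") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("probe_index not contiguous from 1 in probe set(s): ",
         paste(head(bad$probeset_id, 5), collapse = ", "))
  }
  if ("mm_probe_id" %in% names(l)) {
    mm <- l$mm_probe_id[!is.na(l$mm_probe_id)]
    if (anyDuplicated(mm)) stop("duplicate mm_probe_id in layout")
    if (length(intersect(mm, l$probe_id))) {
      stop("mm_probe_id values collide with PM probe IDs")
    }
  }
  tibble::as_tibble(l)
}

#' Write a chip layout
#'
#' @param layout Layout tibble (see [read_layout()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(validate_layout(layout), path)
  invisible(path)
}

#' Construct a probe mask
#'
#' A probe mask is the set of probes excluded from summarization, with
#' provenance: the intensity threshold it was built at, the species whose
#' samples drove the decision, and the masking fraction P.
#'
#' @param probes Tibble with columns `probeset_id`, `probe_id` (may have
#'   zero rows for an empty mask).
#' @param threshold Non-negative intensity threshold.
#' @param species Species label.
#' @param p_fraction Masking fraction P in (0, 1].
#' @param created_from Free-text provenance string.
#' @return A `probe_mask` tibble sorted by `probeset_id`, `probe_id`, with
#'   the provenance carried in attributes.
#' @export
probe_mask <- function(probes, threshold, species, p_fraction,
                       created_from = "crossmask") {
  stopifnot(is.numeric(threshold), threshold >= 0,
            is.numeric(p_fraction), p_fraction > 0, p_fraction <= 1)
  probes <- tibble::as_tibble(probes)[c("probeset_id", "probe_id")]
  probes <- dplyr::arrange(probes, .data$probeset_id, .data$probe_id)
  structure(probes,
            class = c("probe_mask", class(probes)),
            threshold = threshold,
            species = species,
            p_fraction = p_fraction,
            created_from = created_from)
}

#' @export
print.probe_mask <- function(x, ...) {
  cat(sprintf("<probe_mask> %d masked probes | threshold=%g species=%s P=%.4f\n",
              nrow(x), attr(x, "threshold"), attr(x, "species"),
              attr(x, "p_fraction")))
  NextMethod()
}

#' Write / read a probe mask file
#'
#' The on-disk dialect is plain text: `#`-prefixed `key=value` header lines
#' (threshold, species, p_fraction, created_from), then one tab-separated
#' `probeset_id probe_id` line per masked probe, sorted lexicographically.
#' Writing then reading is the identity, and rewriting a read mask is
#' byte-identical.
#'
#' @param mask A `probe_mask` (see [probe_mask()]).
#' @param path File path.
#' @param layout Optional layout tibble; if supplied on read, masked probes
#'   are checked against the layout's probe IDs.
#' @return `write_mask_file()` returns `path` invisibly; `read_mask_file()`
#'   returns a `probe_mask`.
#' @export
write_mask_file <- function(mask, path) {
  stopifnot(inherits(mask, "probe_mask"))
  hdr <- c(
    sprintf("# threshold=%.10g", attr(mask, "threshold")),
    sprintf("# species=%s", attr(mask, "species")),
    sprintf("# p_fraction=%.10g", attr(mask, "p_fraction")),
    sprintf("# created_from=%s", attr(mask, "created_from"))
  )
  body <- if (nrow(mask)) paste(mask$probeset_id, mask$probe_id, sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_mask_file
#' @export
read_mask_file <- function(path, layout = NULL) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  meta <- setNames(vals, keys)
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    probes <- tibble::tibble(probeset_id = vapply(parts, `[`, "", 1L),
                             probe_id = vapply(parts, `[`, "", 2L))
  } else {
    probes <- tibble::tibble(probeset_id = character(), probe_id = character())
  }
  if (!is.null(layout)) {
    unknown <- setdiff(probes$probe_id, layout$probe_id)
    if (length(unknown)) {
      stop("mask file names probe(s) absent from layout: ",
           paste(head(unknown, 5), collapse = ", "))
    }
  }
  probe_mask(probes,
             threshold = as.numeric(meta[["threshold"]]),
             species = meta[["species"]],
             p_fraction = as.numeric(meta[["p_fraction"]]),
             created_from = meta[["created_from"]])
}

#' Write / read a probe-set expression matrix
#'
#' The main file holds `probeset_id` plus one log2-expression column per
#' sample; the number of probes each value was summarized from is written to
#' a sidecar file `<path>.probes_used.tsv`.
#'
#' @param expr Expression tibble with columns `probeset_id`, `probes_used`,
#'   then samples.
#' @param path File path.
#' @return `write_expression()` returns `path` invisibly; `read_expression()`
#'   returns the expression tibble (with `probes_used` `NA` if the sidecar
#'   file is missing).
#' @export
write_expression <- function(expr, path) {
  stopifnot(all(c("probeset_id", "probes_used") %in% names(expr)))
  readr::write_tsv(expr[setdiff(names(expr), "probes_used")], path)
  readr::write_tsv(expr[c("probeset_id", "probes_used")],
                   paste0(path, ".probes_used.tsv"))
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(probeset_id = readr::col_character(),
                                               .default = readr::col_double()))
  sidecar <- paste0(path, ".probes_used.tsv")
  if (file.exists(sidecar)) {
    pu <- readr::read_tsv(sidecar, show_col_types = FALSE,
                          col_types = readr::cols(probeset_id = readr::col_character(),
                                                  probes_used = readr::col_integer()))
    x <- dplyr::left_join(x, pu, by = "probeset_id")
  } else {
    x$probes_used <- NA_integer_
  }
  dplyr::relocate(x, "probeset_id", "probes_used")
}
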