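#' Parameters for the two-species synthetic chip experiment
#'
#' The generator emulates the structure the masking method assumes: one chip
#' design hybridized with two closely related species across several tissues
#' and replicates, with shared tissue expression programs, per-probe
#' affinities, and a planted subset of probes attenuated in the non-target
#' (CSH) species because they target inter-species variable regions.
#'
#' Defaults: gene/tissue log2 means ~ Normal(8, 2); DE genes (fraction
#' `frac_de`) have one tissue shifted by `de_log2_effect` with random sign;
#' probe affinities ~ Normal(0, `affinity_sd`) on the log2 scale; ISV probes
#' (fraction `frac_isv_probes`) keep only a Uniform(`attenuation_range`)
#' multiple of their hybridization signal in the CSH species — a few percent
#' at most, reflecting how strongly central mismatches in 25-mer probes
#' suppress hybridization; optical background ~ Normal(`background_mean`,
#' `background_sd`) is added on the linear scale (draws below 1 are
#' redrawn); MM probes receive background plus `mm_crosstalk` times their
#' PM's signal component.
#'
#' @param n_probesets Number of probe sets (genes).
#' @param probes_per_set PM probes per probe set (default 11).
#' @param tissues Character vector of tissue labels.
#' @param replicates Replicates per tissue per species.
#' @param frac_de Fraction of genes differentially expressed.
#' @param de_log2_effect Log2 shift of the affected tissue in DE genes.
#' @param frac_isv_probes Fraction of PM probes attenuated in the CSH
#'   species.
#' @param attenuation_range Length-2 multiplicative factor range in (0, 1),
#'   low < high.
#' @param affinity_sd SD of per-probe log2 affinities.
#' @param noise_sd_log2 SD of per-measurement log2 noise.
#' @param background_mean,background_sd Optical background (linear scale).
#' @param mm_crosstalk Fraction of the PM signal leaking into the MM probe.
#' @param species_target,species_csh Species labels.
#' @param frac_pathogen Fraction of probe sets tagged as pathogen controls
#'   (excluded by default in [anova_de()]).
#' @param n_classes Number of synthetic functional classes written alongside
#'   the data (stand-ins for curated functional bins).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the parameters and this seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_probesets = 1000, probes_per_set = 11,
                       tissues = c("nodule", "leaf", "root"),
                       replicates = 3, frac_de = 0.15, de_log2_effect = 2,
                       frac_isv_probes = 0.38,
                       attenuation_range = c(5e-4, 0.01),
                       affinity_sd = 1, noise_sd_log2 = 0.4,
                       background_mean = 50, background_sd = 10,
                       mm_crosstalk = 0.05,
                       species_target = "Gm", species_csh = "Pv",
                       frac_pathogen = 0, n_classes = 20, seed = 1) {
  p <- list(n_probesets = n_probesets, probes_per_set = probes_per_set,
            tissues = tissues, replicates = replicates, frac_de = frac_de,
            de_log2_effect = de_log2_effect,
            frac_isv_probes = frac_isv_probes,
            attenuation_range = attenuation_range, affinity_sd = affinity_sd,
            noise_sd_log2 = noise_sd_log2, background_mean = background_mean,
            background_sd = background_sd, mm_crosstalk = mm_crosstalk,
            species_target = species_target, species_csh = species_csh,
            frac_pathogen = frac_pathogen, n_classes = n_classes, seed = seed)
  for (f in c("frac_de", "frac_isv_probes", "frac_pathogen")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (length(attenuation_range) != 2 ||
      attenuation_range[1] <= 0 || attenuation_range[2] >= 1 ||
      attenuation_range[1] >= attenuation_range[2]) {
    stop("attenuation_range must be (low, high) with 0 < low < high < 1")
  }
  if (n_probesets < 1 || probes_per_set < 1 || replicates < 1) {
    stop("n_probesets, probes_per_set, replicates must be positive")
  }
  if (background_mean <= 0 || background_sd <= 0 || noise_sd_log2 < 0 ||
      affinity_sd < 0 || mm_crosstalk < 0 || de_log2_effect < 0) {
    stop("dispersion/scale parameters must be positive")
  }
  structure(p, class = "sim_params")
}

# background draws, redrawn until >= 1 so intensities stay positive
rtrunc_bg <- function(n, mean, sd) {
  b <- stats::rnorm(n, mean, sd)
  while (any(bad <- b < 1)) {
    b[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  b
}

#' Generate a two-species probe-level dataset with known truth
#'
#' Draws, in a fixed documented order under one seeded stream: gene/tissue
#' log2 means, differential-expression assignments, probe affinities, ISV
#' probe flags and attenuation factors, then per-species measurement noise,
#' optical backgrounds and MM backgrounds. PM intensity is
#' `2^(mu_gt + affinity + noise) * delta + background`, where `delta` is the
#' attenuation (1 for conserved probes, the drawn factor for ISV probes in
#' the CSH species only); MM intensity is `background + mm_crosstalk *
#' signal`.
#'
#' @param params A [sim_params()] list.
#' @return A list with `intensities` (tibble, PM and MM rows for all samples
#'   of both species), `layout`, `design`, `classes` (synthetic functional
#'   bins) and `truth` (list: `isv_probes`, `de_genes` tibble with the
#'   shifted tissue and sign, `gene_means` wide tibble of true log2 means
#'   per tissue).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    ng <- p$n_probesets
    k <- p$probes_per_set
    nt <- length(p$tissues)
    np <- ng * k

    ps_ids <- sprintf("PS%05d", seq_len(ng))
    probe_ids <- paste0(rep(ps_ids, each = k), ":", rep(seq_len(k), ng))
    mm_ids <- paste0(probe_ids, ":mm")

    # 1. gene baselines and tissue programs
    baseline <- stats::rnorm(ng, 8, 2)
    is_de <- stats::runif(ng) < p$frac_de
    shift_tissue <- sample(p$tissues, ng, replace = TRUE)
    shift_sign <- sample(c(-1, 1), ng, replace = TRUE)
    mu <- matrix(baseline, ng, nt, dimnames = list(ps_ids, p$tissues))
    idx <- cbind(which(is_de), match(shift_tissue[is_de], p$tissues))
    mu[idx] <- mu[idx] + shift_sign[is_de] * p$de_log2_effect

    # 2. probe affinities, ISV flags, attenuation
    affinity <- stats::rnorm(np, 0, p$affinity_sd)
    is_isv <- stats::runif(np) < p$frac_isv_probes
    delta <- rep(1, np)
    delta[is_isv] <- stats::runif(sum(is_isv), p$attenuation_range[1],
                                  p$attenuation_range[2])

    # 3. pathogen tags and synthetic functional classes
    organism <- rep(p$species_target, ng)
    if (p$frac_pathogen > 0) {
      n_path <- round(p$frac_pathogen * ng)
      pick <- sample(ng, n_path)
      organism[pick] <- rep_len(c("Phytophthora sojae", "Heterodera glycines"),
                                n_path)
    }
    class_ids <- sprintf("BIN%02d", sample(p$n_classes, ng, replace = TRUE))

    design <- tidyr::expand_grid(
      species = c(p$species_target, p$species_csh),
      tissue = p$tissues,
      replicate = seq_len(p$replicates)
    )
    design$sample_id <- paste(design$species, design$tissue,
                              design$replicate, sep = "_")
    design <- design[c("sample_id", "species", "tissue", "replicate")]

    # 4. per-species intensities (target first, then CSH)
    mu_probe <- mu[rep(seq_len(ng), each = k), , drop = FALSE]
    one_species <- function(species) {
      d <- design[design$species == species, ]
      pm <- matrix(0, np, nrow(d), dimnames = list(probe_ids, d$sample_id))
      mmx <- matrix(0, np, nrow(d), dimnames = list(mm_ids, d$sample_id))
      att <- if (species == p$species_csh) delta else rep(1, np)
      for (j in seq_len(nrow(d))) {
        eps <- stats::rnorm(np, 0, p$noise_sd_log2)
        signal <- 2^(mu_probe[, d$tissue[j]] + affinity + eps) * att
        pm[, j] <- signal + rtrunc_bg(np, p$background_mean, p$background_sd)
        mmx[, j] <- rtrunc_bg(np, p$background_mean, p$background_sd) +
          p$mm_crosstalk * signal
      }
      rbind(pm, mmx)
    }
    m_target <- one_species(p$species_target)
    m_csh <- one_species(p$species_csh)

    intensities <- matrix_to_wide(cbind(m_target, m_csh), "probe_id")
    layout <- tibble::tibble(
      probeset_id = rep(ps_ids, each = k),
      probe_id = probe_ids,
      probe_index = rep(seq_len(k), ng),
      mm_probe_id = mm_ids,
      organism = rep(organism, each = k)
    )
    truth <- list(
      isv_probes = probe_ids[is_isv],
      de_genes = tibble::tibble(
        probeset_id = ps_ids[is_de],
        shifted_tissue = shift_tissue[is_de],
        sign = shift_sign[is_de],
        log2_effect = p$de_log2_effect
      ),
      gene_means = matrix_to_wide(mu, "probeset_id")
    )
    list(intensities = intensities, layout = layout, design = design,
         classes = tibble::tibble(probeset_id = ps_ids, class_id = class_ids),
         truth = truth, params = p)
  })
}

#' How well does a mask recover the planted ISV probes?
#'
#' Compares a probe mask against the generator's truth. By default the
#' evaluation is restricted to probes of expressed genes (true mean log2
#' expression at or above `expression_floor`): an unexpressed gene's probes
#' sit at background in both species, so divergence is unidentifiable there
#' by construction.
#'
#' @param mask A `probe_mask`.
#' @param truth Truth list from [simulate_dataset()].
#' @param layout Layout tibble from the same simulation.
#' @param expressed_only Restrict to expressed genes (default TRUE).
#' @param expression_floor Minimum true mean log2 expression, default 6.
#' @return One-row tibble: `sensitivity` (ISV probes masked; `NA` when no
#'   ISV probes), `specificity` (conserved probes retained), `precision`
#'   (masked probes that are ISV; `NA` for an empty mask), plus the counts.
#' @export
evaluate_mask_recovery <- function(mask, truth, layout,
                                   expressed_only = TRUE,
                                   expression_floor = 6) {
  pm_probes <- layout$probe_id
  if (expressed_only) {
    gm <- wide_to_matrix(truth$gene_means, "probeset_id")
    expressed <- rownames(gm)[rowMeans(gm) >= expression_floor]
    pm_probes <- layout$probe_id[layout$probeset_id %in% expressed]
  }
  isv <- intersect(truth$isv_probes, pm_probes)
  conserved <- setdiff(pm_probes, truth$isv_probes)
  masked <- intersect(mask$probe_id, pm_probes)
  tp <- length(intersect(masked, isv))
  tibble::tibble(
    sensitivity = if (length(isv)) tp / length(isv) else NA_real_,
    specificity = if (length(conserved)) {
      length(setdiff(conserved, masked)) / length(conserved)
    } else NA_real_,
    precision = if (length(masked)) tp / length(masked) else NA_real_,
    n_isv = length(isv),
    n_conserved = length(conserved),
    n_masked = length(masked)
  )
}

#' Before/after masking comparison of differential-expression recovery
#'
#' Scores two differential-expression tables over the same probe-set
#' universe against the generator's truth: the fraction of true DE genes
#' called significant (sensitivity) and the mean absolute log2 ratio
#' measured on true DE genes (fold-change compression: attenuated probes
#' pull CSH ratios toward zero, so masking should raise this toward the
#' planted effect size).
#'
#' @param de_before,de_after `crossmask_de` tables from [anova_de()] on the
#'   unmasked and masked data.
#' @param truth Truth list from [simulate_dataset()].
#' @return One-row tibble with `sensitivity_before`, `sensitivity_after`,
#'   `mean_abs_log2fc_before`, `mean_abs_log2fc_after` (all `NA` when the
#'   truth holds no DE genes).
#' @export
evaluate_de_improvement <- function(de_before, de_after, truth) {
  if (!setequal(de_before$probeset_id, de_after$probeset_id)) {
    stop("the two DE tables cover different probe-set universes")
  }
  true_de <- truth$de_genes$probeset_id
  if (length(true_de) == 0) {
    return(tibble::tibble(sensitivity_before = NA_real_,
                          sensitivity_after = NA_real_,
                          mean_abs_log2fc_before = NA_real_,
                          mean_abs_log2fc_after = NA_real_))
  }
  score <- function(de) {
    hit <- de$probeset_id %in% true_de
    list(
      sens = sum(de$significant & hit) / length(true_de),
      fc = mean(de$max_abs_log2fc[hit])
    )
  }
  b <- score(de_before)
  a <- score(de_after)
  tibble::tibble(
    sensitivity_before = b$sens,
    sensitivity_after = a$sens,
    mean_abs_log2fc_before = b$fc,
    mean_abs_log2fc_after = a$fc
  )
}
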