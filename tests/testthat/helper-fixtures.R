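# Shared fixtures, built in code. The default simulation and its
# preprocessed/swept derivatives are cached so several test files can reuse
# them without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the study-condition dataset: 2 species x 3 tissues x 3 replicates
default_sim <- function() {
  cached("default_sim", simulate_dataset(sim_params(seed = 1)))
}

# background-corrected, quantile-normalized PM intensities for one species
preprocessed_species <- function(sim, species) {
  cached(paste0("prep_", species), {
    ids <- sim$design$sample_id[sim$design$species == species]
    x <- sim$intensities[sim$intensities$probe_id %in% sim$layout$probe_id,
                         c("probe_id", ids)]
    quantile_normalize(background_correct(x))
  })
}

# threshold series of the method, with an unmasked anchor at 0
full_thresholds <- function() {
  c(0, 5, 7, 8, 10, 13, 15, 20, 30, 40, 60, 80, 100, 120, 160, 320, 640,
    1280, 2560)
}

default_sweep <- function() {
  cached("default_sweep", {
    sim <- default_sim()
    run_sweep(sim$intensities, sim$intensities, sim$layout, sim$design,
              species_csh = sim$params$species_csh,
              species_target = sim$params$species_target,
              thresholds = full_thresholds(),
              tissue_a = "nodule", tissue_b = "leaf")
  })
}

# a small hand-buildable layout: n_sets probe sets of k probes
toy_layout <- function(n_sets = 3, k = 11, mm = FALSE) {
  ps <- sprintf("TS%03d", seq_len(n_sets))
  out <- tibble::tibble(
    probeset_id = rep(ps, each = k),
    probe_id = paste0(rep(ps, each = k), ":", rep(seq_len(k), n_sets)),
    probe_index = rep(seq_len(k), n_sets)
  )
  if (mm) out$mm_probe_id <- paste0(out$probe_id, ":mm")
  out
}

toy_design <- function(species = "Pv", tissues = c("nodule", "leaf", "root"),
                       replicates = 3) {
  d <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                   species = species, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste(d$species, d$tissue, d$replicate, sep = "_"),
    species = d$species, tissue = d$tissue, replicate = d$replicate
  )
}

# intensity tibble from a plain matrix
toy_intensities <- function(m, probe_ids = rownames(m),
                            sample_ids = colnames(m)) {
  rownames(m) <- probe_ids
  colnames(m) <- sample_ids
  out <- tibble::as_tibble(m)
  tibble::add_column(out, probe_id = probe_ids, .before = 1)
}

# mask over explicit probe ids, with layout lookup
mask_of <- function(layout, probe_ids, threshold = 1, species = "Pv",
                    p_fraction = 7 / 9) {
  probe_mask(layout[layout$probe_id %in% probe_ids,
                    c("probeset_id", "probe_id")],
             threshold = threshold, species = species,
             p_fraction = p_fraction)
}
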