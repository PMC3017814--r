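# crossmask

Probe masking for cross-species hybridization (CSH) microarray data.

When RNA from one species is hybridized to an expression array designed for
a close relative — common practice for crops and other organisms without
their own chip — probes overlapping inter-species variable (ISV) sequence
regions bind poorly and sit at optical background in every sample. The two
symptoms are reduced detection sensitivity and compressed fold changes.
`crossmask` implements the intensity-threshold masking strategy that
repairs both without needing any sequence from the CSH species, plus the
surrounding analysis stack: masked RMA summarization, MAS5-style detection
calls, ANOVA differential expression, conservation classification of probe
sets, Fisher-exact over-representation, and a synthetic two-species data
generator with planted ground truth for validating the whole pipeline.

## The method

Each gene is measured by a probe set of (typically) 11 perfect-match
probes. For one species hybridized as `S` tissue types × `R` replicates
(`Ts = R·S` arrays), a probe is **retained** at intensity threshold *t* iff
at least `R` of its `Ts` background-corrected, quantile-normalized signals
exceed *t* — a working probe for a gene expressed in even one tissue clears
this bar. Equivalently it is **masked** when it sits at or below *t* in at
least a fraction

P = (Ts − R + 1) / Ts

of the arrays; for the canonical 3 × 3 design, P = 7/9 ≈ 0.78. Masked
probes are dropped during RMA median-polish summarization; a probe set
survives while at least one probe does.

The threshold itself is chosen by a sweep: the target species' unmasked
data provides reference tissue contrasts, and each candidate threshold is
scored by (a) the number of *commonly-selected genes* (≥ 2-fold tissue
difference in both species — sensitivity) and (b) the Pearson correlation
of the two species' per-gene log2 tissue ratios over that set (accuracy).
`select_threshold()` picks the correlation optimum subject to retaining at
least 95% of the chip's probe sets.

After masking, the retained-probe count per probe set doubles as a
sequence-conservation proxy: 10–11 retained ⇒ highly conserved, 1–2 ⇒
hyper-variable, with functional enrichment of those groups assessed by a
Bonferroni-corrected Fisher exact test reported as signed z-values.

## Worked example

Everything below is computed from the shipped synthetic generator — two
species × three tissues × three replicates on one 1000-probe-set chip
design, with 38% of probes attenuated in the CSH species ("Pv"); the
target species is "Gm".

```r
library(crossmask)

sim <- simulate_dataset(sim_params(seed = 1))
sw <- run_sweep(sim$intensities, sim$intensities, sim$layout, sim$design,
                species_csh = "Pv", species_target = "Gm",
                thresholds = c(0, 5, 10, 20, 40, 80, 160, 320, 640),
                tissue_a = "nodule", tissue_b = "leaf")
sel <- select_threshold(sw)
tidy(annotate_selection(sw, sel))
#> # A tibble: 9 × 6
#>   threshold n_probes_retained n_probesets_retained n_common pearson_r selected
#>       <dbl>             <int>                <int>    <int>     <dbl> <lgl>
#> 1         0             11000                 1000       66     0.964 FALSE
#> 2         5             11000                 1000       66     0.964 FALSE
#> 3        10              9110                 1000       74     0.968 FALSE
#> 4        20              6823                  996       74     0.972 TRUE
#> 5        40              6227                  969       74     0.972 FALSE
#> 6        80              5533                  932       74     0.972 FALSE
#> 7       160              4531                  856       74     0.973 FALSE
#> 8       320              3392                  723       74     0.970 FALSE
#> 9       640              2267                  546       66     0.977 FALSE
```

Masking at the selected threshold and scoring against the planted truth:

```r
d  <- sim$design
pv <- sim$intensities[c("probe_id", d$sample_id[d$species == "Pv"])]
pv <- pv[pv$probe_id %in% sim$layout$probe_id, ]
pv <- quantile_normalize(background_correct(pv))

mask <- build_mask(pv, sim$layout, d, "Pv", sel)
mask
#> <probe_mask> 4177 masked probes | threshold=20 species=Pv P=0.7778

evaluate_mask_recovery(mask, sim$truth, sim$layout)
#> # A tibble: 1 × 6
#>   sensitivity specificity precision n_isv n_conserved n_masked
#> 1       0.918       0.998     0.996  3416        5648     3150
```

92% of the planted ISV probes (on expressed genes) are caught, with 0.2%
of conserved probes lost. The downstream payoff — differential expression
before and after masking:

```r
de_before <- anova_de(summarize_rma(pv, sim$layout), d)
de_after  <- anova_de(summarize_rma(pv, sim$layout, mask), d)
glance(de_before); glance(de_after)
#>   n_tested n_significant  p_cut fold_cut max_fdr_significant
#> 1     1000            87 0.0001        2             0.00112
#> 1      996           123 0.0001        2            0.000749

shared <- intersect(de_before$probeset_id, de_after$probeset_id)
evaluate_de_improvement(de_before[de_before$probeset_id %in% shared, ],
                        de_after [de_after$probeset_id  %in% shared, ],
                        sim$truth)
#>   sensitivity_before sensitivity_after mean_abs_log2fc_before mean_abs_log2fc_after
#> 1              0.544             0.769                   1.48                  2.05
```

Masking lifts recovery of true differential genes from 54% to 77% and
decompresses the measured effect size from 1.48 back to the planted 2.0
log2 units. Conservation classification of the same mask:

```r
table(classify_conservation(mask, sim$layout)$group)
#>       all_masked   hyper_variable     intermediate highly_conserved
#>                4               22              899               75
```

`autoplot()` methods exist for sweeps and for `pca_overview()` results;
`tidy()`/`glance()` follow the usual conventions.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
crossmask simulate --n-probesets 5000 --seed 9 --out-dir sim/
crossmask sweep --csh sim/intensities_Pv.tsv --target sim/intensities_Gm.tsv \
  --layout sim/layout.tsv --design sim/design.tsv \
  --species-csh Pv --species-target Gm \
  --thresholds 5,7,8,10,13,15,20,30,40,60,80,100,120,160,320,640 \
  --tissues nodule,leaf --out sweep.tsv
crossmask mask --intensities sim/intensities_Pv.tsv --layout sim/layout.tsv \
  --design sim/design.tsv --species Pv --threshold 20 --out Pv20.mask
crossmask summarize --intensities sim/intensities_Pv.tsv --layout sim/layout.tsv \
  --design sim/design.tsv --species Pv --mask Pv20.mask --out Pv_expr.tsv
crossmask de --expr Pv_expr.tsv --design sim/design.tsv --layout sim/layout.tsv --out de.tsv
crossmask classify --mask Pv20.mask --layout sim/layout.tsv --out groups.tsv
crossmask overrep --selection genes.txt --classes sim/classes.tsv \
  --universe all.txt --out overrep.tsv
```

All interchange formats are plain TSV (mask files are `#`-headed
two-column text); see `?read_intensities`, `?read_layout`,
`?write_mask_file`.

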