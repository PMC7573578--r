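# gfoffset

Gradient-forest genomic offset and assisted-migration planning for
monsoon-adapted crops.

## What this package does

Landrace panels of staple crops such as pearl millet carry allele
frequencies shaped by local climate — above all by monsoon timing, which
sets sowing dates and growing seasons across the Sahel. `gfoffset`
implements a complete landscape-genomics pipeline around that observation,
for researchers studying crop adaptation under climate change:

1. **Monsoon-anchored climate metrics** — detects monsoon onset from daily
   rainfall (20 mm over 3 days, no 7-day dry spell in the following 20
   days; all constants configurable) and computes a catalog of 157
   agro-climate metrics: onset plus 26 base statistics of precipitation,
   mean/max/min temperature and shortwave radiation in each of six windows
   of 30–180 days after onset, with a Pearson-0.7 greedy decorrelation
   filter.
2. **Turnover models (gradient forest)** — per-SNP regression random
   forests (500 trees/SNP, MAF > 10%) linking allele frequencies to the
   climate metrics. Per-split impurity reductions are binned along each
   predictor, density-normalised, R²-weighted over the SNPs with
   out-of-bag R² > 0, and cumulated into monotone turnover functions
   `F_p` that map climate into genomic-composition space.
3. **Genomic vulnerability (offset)** — the Euclidean distance
   `‖F(x_future) − F(x_current)‖₂` per pixel, computed separately for each
   climate model of an ensemble inside the convex hull of the landrace
   coordinates, summarised as multi-model mean, population SD, CV, and a
   stippling flag (mean > 2·SD). Per-landrace offsets to a common-garden
   site are correlated with yield traits as an empirical validation.
4. **Assisted migration** — DBSCAN clustering (great-circle distances) of
   the 10% most vulnerable pixels per climate model, focal-pixel selection,
   and donor search under optimal (global minimum ED), near-optimal
   (closest pixel within the 1% lowest ED) and sub-optimal (5%) strategies,
   with migration distance, migration load (the donor's ED) and
   transboundary flags, pooled across the ensemble.
5. **Flowering-time association** — ridge-flavoured latent-factor
   association (PCA factors, genomic-control calibration,
   Benjamini–Hochberg FDR at 5%) plus a Wilcoxon comparison showing that
   phenotype-associated SNPs are better predicted by climate.
6. **Synthetic data** — a seeded generator emulating a West-African
   0.5° grid with a latitudinal monsoon gradient, logistic allele-frequency
   clines, neutral SNPs, bimodal flowering time and yield declining with
   climate mismatch, so every stage is testable offline.

## Worked example

```r
library(gfoffset)

scenario <- synthetic_scenario(
  lat_range = c(9, 15), lon_range = c(-7, 0),
  n_landraces = 80, n_adaptive_snps = 8, n_neutral_snps = 32,
  onset_shift_days = 15, precip_scale = 0.85, seed = 7)
config <- pipeline_config(n_trees = 100, n_models = 2, seed = 7,
                          use_uncorrelated = TRUE, eps_km = 200)
run <- run_pipeline(scenario, config, outdir = "example-out")

run$fits[[1]]
sort(run$fits[[1]]$importance, decreasing = TRUE)[1:3]
mean(run$vmap$summary$mean)
run$migration_summary[, c("strategy", "n_areas", "dist_mean",
                          "transboundary_pct", "load_mean")]
run$yield_validation
```

This prints (R 4.3.3, seed 7):

```
turnover_model: 29 predictors, 39 SNPs (10 with R2 > 0), 100 trees/SNP
top predictors:
    onset_day tmean_mean_30   srad_min_30   srad_min_90   srad_max_30
      0.34500       0.06945       0.06840       0.03988       0.03971

mean offset: 0.1129

      strategy n_areas dist_mean transboundary_pct load_mean
       optimal       2     534.0                50   0.01452
  near_optimal       2     507.7               100   0.01537
   sub_optimal       2     444.8                 0   0.01875

            trait      r      p  n
1 seed_weight_100 -0.201 0.0745 80
2    spike_weight -0.220 0.0503 80
3 seeds_per_plant -0.220 0.0500 80
```

Reading the output: the fitted turnover model ranks the planted driver
(`onset_day`, the monsoon-onset day) first by aggregate importance, and
the 10 SNPs with out-of-bag R² > 0 are the clinal (adaptive plus
MAF-surviving) ones. The 15-day monsoon delay produces a positive mean
offset (0.113) over the cultivation hull. The migration table shows the
strategy trade-off: donors get geographically closer from optimal to
sub-optimal (534 → 445 km) while the residual migration load grows
(0.0145 → 0.0188). The yield validation recovers the planted negative
vulnerability–yield relationship in sign for all three traits; at this
deliberately small panel (n = 80) the p-values sit at the 0.05 boundary,
and at the recovery-trial size (n = 150, 200 SNPs) the same check is
significant in 20/20 seeds (see below).

## Further reading

The methods vignette (`vignettes/genomic-offset-methods.Rmd`) documents the
model and its assumptions, every tunable constant with units and defaults,
what the synthetic generator does and does not emulate, numerical choices
(tie-breaks, clamping, SD conventions) and known limitations.
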