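---
title: "Methods: gradient-forest genomic offset and assisted migration for monsoon-adapted crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-forest genomic offset and assisted migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Smallholder farmers across the Sahel grow locally adapted landraces of
staple cereals such as pearl millet. Each landrace carries allele
frequencies shaped by the climate of its home site — above all by the
timing and intensity of the monsoon, which sets the sowing date and the
growing season. As the climate shifts, the genotype a site's environment
"expects" moves away from the genotype its landraces actually carry. This
package quantifies that gap (genomic vulnerability, or genomic offset),
maps it across a cultivation area under an ensemble of future climate
projections, and asks which existing landrace could be moved where to close
the gap (assisted migration), at what geographic cost, and with how much
residual maladaptation (migration load).

# Monsoon-anchored climate metrics

All climate predictors are aligned to the local monsoon onset rather than
the calendar, because sowing follows the rains. `detect_monsoon_onset()`
implements a standard Sahelian agronomic sowing rule: onset is the first
day with at least 20 mm of rain accumulated over 3 consecutive days, not
followed within the next 20 days by a dry spell of 7 or more consecutive
days each receiving under 1 mm. All five constants are arguments of
`onset_rule()`: published onset definitions differ in detail, so the rule
is a configurable registry rather than a hard-coded formula. A year with no
qualifying day returns a missing onset and the pixel is dropped from the
metric table with a warning (an error would be wrong: desert-edge pixels
legitimately have no monsoon).

The catalog then evaluates 26 base metrics inside each of six half-open
windows `[onset, onset + W)` for `W` in 30, 60, 90, 120, 150, 180 days:

* precipitation (10): total, mean, max daily, wet days (> 1 mm), heavy days
  (> 20 mm), longest dry spell, longest wet spell, simple daily intensity
  (total / wet days, 0 when the window is dry), 95th percentile of daily
  rain, dry days;
* each temperature family — mean, maximum, minimum near-surface air
  temperature (4 each): mean, min, max, and a count of hot days
  (tmean > 30, tmax > 35, tmin > 25 degrees C);
* shortwave radiation (4): mean, min, max, and low-radiation (cloudy)
  days (< 150 W/m2).

With the onset day itself this yields 1 + 6 x 26 = 157 metrics. The exact
composition of the 26 is a design choice of this package: the registry
(`metric_registry()`) is data-driven and swappable, and the catalog size is
what downstream code relies on, not any individual member. Landrace sites
take the metrics of their containing 0.5-degree pixel; no interpolation.

Because windowed metrics overlap heavily, `select_uncorrelated()` provides
the standard greedy decorrelation filter: walk the metrics in a fixed order
(catalog order, or an importance ranking) and keep a metric only if its
absolute Pearson correlation with everything already kept is at most 0.7.
Zero-variance metrics are excluded with a warning since their correlation
is undefined.

# The turnover model

`gf_fit()` is a gradient-forest engine written for this package (R driver,
C++ forest): one regression random forest per SNP, frequency regressed on
all climate predictors, with 500 trees per SNP by default, `mtry = p/3`
predictors sampled per split over the varying predictors, bootstrap per
tree, and variance-reduction (CART) splits down to node size 5. Each forest
records, for every split, the predictor, the split value, and the impurity
decrease; out-of-bag predictions give a per-SNP cross-validated R2, clamped
below at 0. Only SNPs with R2 > 0 — those with genuine predictive power —
contribute to the turnover aggregation.

Per predictor, split improvements are pooled over predictive SNPs, each
SNP's contributions weighted by `R2 * improvement / total improvement` so a
SNP distributes its explained variance over its own splits. The pooled mass
is binned along the predictor (201 bins over the training range), divided
by the empirical density of the predictor's training values — the density
of split opportunities, without which densely sampled regions would look
spuriously important — and rescaled so the curve's total equals the
predictor's aggregate R2-weighted importance. The cumulative sum is the
turnover function `F_p`: a monotone non-decreasing step function with
`F_p(training min) = 0` whose jumps sit where allele frequencies turn over
along the gradient. Jumps are placed at bin right edges, making `F_p`
right-continuous with `F_p(min) = 0` exactly. Outside the training range
the transform clamps to the boundary: cumulative importance is undefined
where no data were seen, and clamping keeps every `F_p` bounded.

Constant predictors are excluded from split sampling (and `mtry` is
computed over varying predictors only), which makes a useful invariant
exact rather than approximate: appending a constant predictor leaves every
other turnover function, and hence every offset, bit-identical.

Choices a practitioner may care about: forests are seeded per SNP
(`seed + SNP index`) so fits are reproducible and SNP-order independent;
negative out-of-bag R2 is evidence of no signal, not negative signal, hence
the clamp; the bin count (201) trades resolution against noise in the
turnover curve and is configurable.

# Genomic offset, ensembles, and validation

`genomic_offset()` is the Euclidean distance between the turnover-space
positions of two climates. `map_offsets()` computes it per pixel between
matched current and future metric tables, separately for each climate model
of an ensemble — each climate model gets its own fitted turnover model,
since each model's present-day climate differs — and restricted to pixels
whose centers fall inside the convex hull of the landrace coordinates (the
cultivation area). Across models it reports the mean, the population SD
(the ensemble is the full set of models under study, not a sample from a
larger one; the convention is recorded in the object), the coefficient of
variation, and a stippling flag marking pixels where the mean exceeds twice
the SD (CV < 0.5), i.e. where the ensemble agrees. When the mean offset is
0 the CV is undefined and reported as `NA` with the stipple flag `FALSE`.

`landrace_site_vulnerability()` runs the same distance between each
landrace's origin climate and one common-garden site, and
`correlate_yield()` tests the expectation that landraces with larger
offsets to the garden yield less there: Pearson r and two-sided p per
yield trait, with missing pairs dropped and counted.

# Assisted migration

For one climate model, `vulnerable_clusters()` takes the pixels above the
0.90 offset quantile (strictly above, so a uniformly zero map has no
vulnerable pixels), clusters them with DBSCAN over great-circle distances
(core point: at least 4 neighbours within `eps_km`; default eps 300 km,
about six 0.5-degree pixels), discards noise and clusters smaller than 4,
and then iteratively merges clusters whose most-vulnerable pixels lie
within 1200 km of each other so the retained vulnerable areas are well
separated. The merge operator (merge closest pair, re-derive focal,
repeat) is this package's reading of a separation rule that could be
formalised several ways; both constants are exposed parameters.

Within each cluster the focal pixel is the offset argmax (ties:
lexicographic coordinates). `donor_search()` then scores every cultivation
pixel j by `ED_j`, the distance between the focal pixel's future
transformed climate and pixel j's current transformed climate. The focal
pixel itself is a legitimate candidate — self-donation means the best
future genotype is already there, with load equal to the pixel's own
offset. Strategies:

* optimal: the global ED minimum;
* near-optimal / sub-optimal: the geographically closest pixel among the
  1% / 5% lowest-ED pixels (rank quantile, `ceiling(n q)`, at least 1).

All strategies share one deterministic ED ranking whose ties are broken by
geographic proximity and then lexicographic coordinates. This matters:
turnover functions are step functions, so distinct pixels can have exactly
equal ED, and a pool truncated under a different tie order could exclude
the optimal donor and violate the expected orderings. With nested pools,
`distance(sub) <= distance(near) <= distance(optimal)` and
`load(optimal) <= load(near), load(sub)` hold on every run by set
inclusion. The chosen donor's ED is the migration load; distances are
great-circle (haversine, sphere radius 6371.0088 km); a donor in a
different country flags the migration as transboundary.
`summarize_migrations()` pools plans across climate models — each model
analysed separately, then combined — reporting per strategy the area count,
distance min/mean/SD/max (sample SD across pooled plans), transboundary
percentage, and load range.

# Flowering-time association

`lfmm_fit()` tests each SNP's frequency against a phenotype while
conditioning on K latent factors taken as the leading principal components
of the centered frequency matrix — the ridge-flavoured, closed-form member
of the latent-factor-mixed-model family, chosen over MCMC variants because
it is deterministic and directly testable (with `K = 0` it collapses
exactly to simple linear regression, which the tests assert to 1e-8).
`choose_k()` picks K from the eigenvalue screeplot by the largest-drop
rule, capped at 10, and accepts an override for K chosen from external
diagnostics such as Q-Q plots (`qq_table()` emits the table). z-scores are
recalibrated by the genomic-inflation factor (median observed chi-square
over its theoretical median) before two-sided p-values; by construction the
calibrated median chi-square equals its theoretical value. Selection is
Benjamini-Hochberg at FDR 5% — deterministic and conservative relative to
pi0-estimating q-value methods, which suit this threshold-based selection.
`compare_r2()` closes the loop: a Wilcoxon rank-sum test of whether the
phenotype-associated SNPs are better predicted by climate (higher turnover
R2) than the panel at large.

# The synthetic generator

`synthetic_scenario()` + `generate_dataset()` produce seeded data with the
statistical structure the analysis assumes, so the whole pipeline is
testable without any download:

* a 0.5-degree West-Africa-like grid whose wet season starts about 5
  days later per degree of latitude (onset near day 95 in the south);
  daily rain is Bernoulli wet days with a sine-envelope intensity, plus a
  seasonal temperature cycle and radiation dipping under monsoon cloud;
* the future member is a deterministic transform of the current one —
  precipitation shifted later by `onset_shift_days` and scaled by
  `precip_scale`, temperatures offset by `warming_c` — so a zero
  perturbation forces bit-identical future climate and therefore exactly
  zero offset everywhere (an end-to-end identity the acceptance tests
  exercise on a 20 x 20 grid);
* adaptive SNPs follow logistic clines on a designated driver metric
  (monsoon onset by default): frequency `plogis(s (z - c))` on the
  standardized driver with SNP-specific thresholds; neutral SNPs get a
  site-independent Beta(2, 2) base; truncated-Gaussian noise (SD 0.05) is
  added and frequencies clipped to [0, 1];
* flowering time is 60 days plus a 50-day effect of the first adaptive
  SNP plus 5-day noise — the steep cline makes causal frequencies nearly
  binary, giving the observed bimodality with modes near 60 and 110 days;
* yield traits decline linearly in the standardized driver distance
  between a landrace's origin and a common-garden pixel near the panel
  centroid (100-seed weight 1.2 g baseline, slope 0.25 per mismatch SD;
  main-spike seed weight 18 g, slope 3.5; seeds per plant as spike weight
  times a productive-tiller count near 2.5).

Default panel dimensions mirror a realistic landrace study: 173 landraces,
10 longitudinal country bands, and a 20 + 180 adaptive/neutral SNP split at
150 landraces in the recovery trials. What the generator does *not*
emulate, deliberately: pool-seq sampling noise (truncated Gaussian on
frequencies, not Beta-binomial read noise), linkage disequilibrium,
isolation-by-distance beyond the country bands, and multi-year climate
variability (one synthetic climate year per period). Passing tests
therefore demonstrate that the estimators recover the structure they were
designed for, not that real pool-seq data meet these assumptions.

# Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the planted structure is
comfortably identifiable: recovery trials use 150 landraces, 200 SNPs, 200
trees per SNP on the decorrelated metric subset, over 20 seeds; the
zero-perturbation identity runs end-to-end on a 20 x 20 pixel grid; oracle
checks use instances of at most 30 elements where brute force is
transparent. Every stochastic step flows from a single integer seed:
generators call `set.seed` on scenario-derived offsets, and each SNP's
forest is seeded as `seed + SNP index`, so identical inputs give
bit-identical outputs (the pipeline writes a config hash and seed into its
manifest, and re-running a config reproduces `summary.json` byte for
byte).

# Known limitations

* Turnover functions are correlational genotype-climate associations;
  offsets are proxies for required genetic change, not predictions of
  fitness loss. The yield validation is the package's empirical anchor.
* The offset treats all predictors through their cumulative importance;
  correlated metrics share importance in a way controlled by the forest,
  not by causal knowledge. The decorrelation filter is available
  (`use_uncorrelated`) and the zero-offset identity is invariant to it.
* DBSCAN results depend on `eps_km`; the default (300 km) matches the
  pixel scale of a subcontinental 0.5-degree analysis and should be
  re-examined for other geographies.
* The ridge LFMM with PCA factors can absorb genuinely adaptive signal
  into the structure correction when the phenotype is collinear with the
  leading cline; the recovery trials quantify the power that remains under
  the default scenario.
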