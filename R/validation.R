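#' One seeded parameter-recovery trial on synthetic clinal data
#'
#' Generates a synthetic panel (default 150 landraces, 20 adaptive + 180
#' neutral SNPs on the default West-African-like grid), fits the turnover
#' model on the decorrelated metric subset, and checks how well the planted
#' structure is recovered: the rank of the driver metric in the aggregate
#' importance, the adaptive-vs-neutral R2 rank-sum test, selection of the
#' planted flowering SNP at FDR 5%, and the sign/significance of the
#' yield-vulnerability correlations at the common-garden site. Intended for
#' simulation-based calibration of the whole pipeline; run over many seeds
#' and inspect the success rates.
#'
#' @param seed integer seed for this trial.
#' @param n_landraces,n_adaptive,n_neutral panel dimensions.
#' @param n_trees trees per SNP forest.
#' @param maf_gf,maf_gwas,fdr_alpha analysis thresholds.
#' @return list: `driver_rank`, `wilcox_p`, `mean_r2_adaptive`,
#'   `mean_r2_neutral`, `causal_selected`, `causal_in_panel`, `yield`
#'   (data.frame of per-trait r/p), `fraction_predicted`.
#' @export
recovery_trial <- function(seed, n_landraces = 150L, n_adaptive = 20L,
                           n_neutral = 180L, n_trees = 200L,
                           maf_gf = 0.10, maf_gwas = 0.05,
                           fdr_alpha = 0.05) {
  sc <- synthetic_scenario(n_landraces = n_landraces,
                           n_adaptive_snps = n_adaptive,
                           n_neutral_snps = n_neutral, seed = seed)
  cl <- generate_climate(sc)
  lr <- generate_landraces(sc, cl$current)
  pm <- compute_metrics(subset_pixels(cl$current, lr$pixel_id))
  sm <- landrace_metrics(pm, lr)
  af <- generate_allele_freqs(sc, lr, sm)
  ph <- generate_phenotypes(sc, lr, af$freqs, af$truth, sm)

  keep <- select_uncorrelated(sm)
  fq <- filter_maf(af$freqs, maf_gf)
  fit <- gf_fit(fq, sm, n_trees = n_trees, seed = seed, predictors = keep)
  imp <- sort(fit$importance, decreasing = TRUE)
  driver_rank <- match(af$truth$driver, names(imp))

  adaptive <- intersect(af$truth$adaptive, names(fit$r2))
  neutral <- setdiff(names(fit$r2), adaptive)
  wilcox_p <- suppressWarnings(
    stats::wilcox.test(fit$r2[adaptive], fit$r2[neutral])$p.value)

  fqg <- filter_maf(af$freqs, maf_gwas)
  causal <- af$truth$adaptive[1]
  causal_in_panel <- causal %in% colnames(fqg)
  causal_selected <- FALSE
  if (causal_in_panel) {
    res <- suppressWarnings(
      lfmm_fit(fqg, ph$flowering_days, K = choose_k(fqg)))
    sel <- fdr_select(res$stats$p, fdr_alpha)
    causal_selected <- sel$selected[match(causal, res$stats$snp)]
  }

  garden <- sm[match(ph$garden_site[1], sm$site_id), , drop = FALSE]
  vuln <- landrace_site_vulnerability(fit, sm, garden)
  yield <- correlate_yield(vuln, ph[, c("id", "seed_weight_100",
                                        "spike_weight", "seeds_per_plant")])

  list(driver_rank = driver_rank, wilcox_p = wilcox_p,
       mean_r2_adaptive = mean(fit$r2[adaptive]),
       mean_r2_neutral = mean(fit$r2[neutral]),
       causal_selected = causal_selected,
       causal_in_panel = causal_in_panel,
       yield = yield,
       fraction_predicted = fraction_predicted(fit)$fraction)
}

#' Run recovery trials over several seeds and summarise success rates
#'
#' @param seeds integer vector of seeds.
#' @param ... passed to [recovery_trial()].
#' @return list: `rates` (named success proportions), `trials` (per-seed
#'   results).
#' @export
recovery_rates <- function(seeds, ...) {
  trials <- lapply(seeds, recovery_trial, ...)
  rates <- c(
    driver_top2 = mean(vapply(trials, function(t)
      t$driver_rank <= 2, logical(1))),
    adaptive_r2_wilcoxon = mean(vapply(trials, function(t)
      t$mean_r2_adaptive > t$mean_r2_neutral && t$wilcox_p < 0.05,
      logical(1))),
    flowering_snp_fdr = mean(vapply(trials, function(t)
      isTRUE(t$causal_selected), logical(1))),
    yield_negative_cor = mean(vapply(trials, function(t)
      all(t$yield$r < 0) && all(t$yield$p < 0.05), logical(1))))
  list(rates = rates, trials = trials)
}
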