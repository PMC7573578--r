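test_that("zero perturbation leaves the future climate identical", {
  sc <- tiny_scenario(onset_shift_days = 0L, precip_scale = 1, warming_c = 0)
  cl <- generate_climate(sc)
  for (v in c("precip", "tmean", "tmax", "tmin", "srad"))
    expect_identical(cl$current[[v]], cl$future[[v]])
})

test_that("generated climate is deterministic under a fixed seed", {
  a <- generate_climate(tiny_scenario(seed = 7L))
  b <- generate_climate(tiny_scenario(seed = 7L))
  expect_identical(a$current$precip, b$current$precip)
  expect_identical(a$future$srad, b$future$srad)
  lr1 <- generate_landraces(tiny_scenario(seed = 7L), a$current)
  lr2 <- generate_landraces(tiny_scenario(seed = 7L), b$current)
  expect_identical(lr1, lr2)
})

test_that("monsoon onset increases with latitude", {
  cl <- generate_climate(tiny_scenario(seed = 2L))
  px <- cl$current$pixels
  i_south <- which(px$lat == min(px$lat))[1]
  i_north <- which(px$lat == max(px$lat))[1]
  o_south <- detect_monsoon_onset(cl$current$precip[i_south, ])
  o_north <- detect_monsoon_onset(cl$current$precip[i_north, ])
  expect_true(o_north > o_south)
})

test_that("future delay shifts every pixel's detected onset later", {
  sc <- tiny_scenario(onset_shift_days = 15L, precip_scale = 1, warming_c = 0)
  cl <- generate_climate(sc)
  for (i in c(1L, 40L, 80L)) {
    oc <- detect_monsoon_onset(cl$current$precip[i, ])
    of <- detect_monsoon_onset(cl$future$precip[i, ])
    expect_identical(of, oc + 15L)
  }
})

test_that("landraces are placed inside the grid with country bands", {
  sc <- synthetic_scenario(n_landraces = 173L, n_countries = 10L, seed = 4L)
  cl <- generate_climate(sc)
  lr <- generate_landraces(sc, cl$current)
  expect_identical(nrow(lr), 173L)
  expect_length(unique(lr$country), 10L)
  expect_true(all(lr$lat >= sc$lat_range[1] & lr$lat <= sc$lat_range[2]))
  expect_true(all(lr$lon >= sc$lon_range[1] & lr$lon <= sc$lon_range[2]))
  expect_true(all(lr$pixel_id %in% cl$current$pixels$pixel_id))

  one <- tiny_scenario(n_countries = 1L)
  lr1 <- generate_landraces(one, generate_climate(one)$current)
  expect_identical(unique(lr1$country), "country01")

  expect_error(generate_landraces(tiny_scenario(n_landraces = 2L), NULL))
})

test_that("allele frequencies are clinal for adaptive SNPs and bounded", {
  ds <- tiny_dataset()
  expect_true(all(ds$freqs >= 0 & ds$freqs <= 1))
  expect_identical(rownames(ds$freqs), ds$landraces$id)
  expect_length(ds$truth$adaptive, 5L)

  # noiseless adaptive SNP is monotone in its driver metric
  sc0 <- tiny_scenario(noise_sd = 0, n_adaptive_snps = 1L,
                       n_neutral_snps = 0L)
  cl <- generate_climate(sc0)
  lr <- generate_landraces(sc0, cl$current)
  pm <- compute_metrics(subset_pixels(cl$current, lr$pixel_id))
  sm <- landrace_metrics(pm, lr)
  af <- generate_allele_freqs(sc0, lr, sm)
  o <- order(sm$onset_day)
  expect_true(all(diff(af$freqs[o, 1]) >= 0))

  # missing site is an error
  expect_error(generate_allele_freqs(sc0, lr, sm[-1, ]), "missing")
})

test_that("near-zero cline steepness makes adaptive SNPs indistinguishable from neutral", {
  # under the null, the adaptive/neutral R2 rank-sum test should be
  # non-significant in at least 90% of seeds
  nonsig <- 0L
  preds <- c("onset_day", "precip_total_90", "tmean_mean_90",
             "srad_mean_90", "tmax_hot_days_90")
  for (s in 1:20) {
    sc <- tiny_scenario(seed = 100L + s, cline_steepness = 0)
    cl <- generate_climate(sc)
    lr <- generate_landraces(sc, cl$current)
    pm <- compute_metrics(subset_pixels(cl$current, lr$pixel_id))
    sm <- landrace_metrics(pm, lr)
    af <- generate_allele_freqs(sc, lr, sm)
    fit <- gf_fit(af$freqs, sm, n_trees = 50L, seed = s,
                  predictors = preds)
    ad <- ds_names <- af$truth$adaptive
    r2a <- fit$r2[ad]
    r2n <- fit$r2[setdiff(names(fit$r2), ad)]
    p <- suppressWarnings(stats::wilcox.test(r2a, r2n)$p.value)
    if (is.na(p) || p >= 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 18L)
})

test_that("phenotype model evaluates the planted linear effects exactly", {
  ds <- tiny_dataset()
  sc <- ds$scenario
  ph <- generate_phenotypes(sc, ds$landraces, ds$freqs, ds$truth,
                            ds$site_metrics, flower_noise_sd = 0)
  causal <- ds$truth$adaptive[1]
  expect_equal(ph$flowering_days, 60 + 50 * ds$freqs[, causal],
               ignore_attr = TRUE)
  # a landrace at frequency 1 flowers at baseline + effect
  fq <- ds$freqs
  fq[3, causal] <- 1
  ph2 <- generate_phenotypes(sc, ds$landraces, fq, ds$truth,
                             ds$site_metrics, flower_noise_sd = 0)
  expect_equal(ph2$flowering_days[3], 110)
  expect_error(generate_phenotypes(sc, ds$landraces, ds$freqs,
                                   list(adaptive = character(0),
                                        driver = "onset_day"),
                                   ds$site_metrics),
               "causal")
})

test_that("flowering time is bimodal under default parameters", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  hits <- 0L
  for (s in 1:20) {
    sc <- synthetic_scenario(n_landraces = 200L, seed = 300L + s)
    cl <- generate_climate(sc)
    lr <- generate_landraces(sc, cl$current)
    pm <- compute_metrics(subset_pixels(cl$current, lr$pixel_id))
    sm <- landrace_metrics(pm, lr)
    af <- generate_allele_freqs(sc, lr, sm)
    ph <- generate_phenotypes(sc, lr, af$freqs, af$truth, sm)
    mc <- mclust::Mclust(ph$flowering_days, G = 1:3, verbose = FALSE)
    if (mc$G >= 2) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("yield declines with climate mismatch", {
  hits <- 0L
  for (s in 1:20) {
    sc <- synthetic_scenario(n_landraces = 173L, seed = 500L + s)
    cl <- generate_climate(sc)
    lr <- generate_landraces(sc, cl$current)
    pm <- compute_metrics(subset_pixels(cl$current, lr$pixel_id))
    sm <- landrace_metrics(pm, lr)
    af <- generate_allele_freqs(sc, lr, sm)
    ph <- generate_phenotypes(sc, lr, af$freqs, af$truth, sm)
    ct <- stats::cor.test(ph$climate_mismatch, ph$seed_weight_100)
    if (ct$estimate < 0 && ct$p.value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
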