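test_that("MAF filtering folds frequencies before thresholding", {
  mk <- function(mu) matrix(rep(mu, each = 30), 30,
                            dimnames = list(NULL, paste0("s", seq_along(mu))))
  f <- mk(c(0.02, 0.09, 0.11, 0.50, 0.91, 0.97))
  expect_equal(unname(folded_maf(f)),
               c(0.02, 0.09, 0.11, 0.50, 0.09, 0.03))
  kept <- filter_maf(f, 0.10)
  expect_identical(colnames(kept), c("s3", "s4"))
  expect_identical(ncol(filter_maf(mk(0.5), 0.10)), 1L)   # maximal MAF kept
  expect_identical(ncol(suppressWarnings(filter_maf(mk(0.95), 0.10))), 0L)
})

test_that("turnover functions start at zero, are monotone, and clamp", {
  fit <- tiny_fit()
  lo <- fit$ranges["lo", ]
  hi <- fit$ranges["hi", ]
  expect_equal(unname(gf_transform(fit, lo)), rep(0, length(lo)))
  # total mass equals the aggregate importance
  expect_equal(unname(gf_transform(fit, hi)), unname(fit$importance))
  expect_true(all(fit$importance >= 0))
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  for (p in fit$predictors)
    expect_true(all(diff(fit$turnover[[p]]$cum) >= -1e-12))

  # componentwise monotonicity on random pairs
  set.seed(1)
  for (i in 1:25) {
    u <- runif(length(lo))
    v <- u + runif(length(lo), 0, 0.5)
    x1 <- lo + u * (hi - lo)
    x2 <- lo + pmin(1, v) * (hi - lo)
    names(x1) <- names(x2) <- fit$predictors
    expect_true(all(gf_transform(fit, x2) - gf_transform(fit, x1) >= -1e-12))
  }

  # beyond the training maximum the transform equals the boundary value
  beyond <- hi * 1.5 + 1
  names(beyond) <- fit$predictors
  expect_equal(gf_transform(fit, beyond), gf_transform(fit, hi))
  expect_error(gf_transform(fit, c(bogus = 1)), "missing predictor")
})

test_that("a noiseless step cline localises the turnover jump at the threshold", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 200
    x <- runif(n, 0, 10)
    cc <- runif(1, 2, 8)
    mt <- data.frame(site_id = sprintf("s%03d", 1:n), lat = 0, lon = 0,
                     metric_x = x)
    f <- matrix(as.numeric(x > cc), n,
                dimnames = list(mt$site_id, "snp1"))
    fit <- gf_fit(f, mt, n_trees = 100L, seed = s)
    tv <- fit$turnover[["metric_x"]]
    mids <- (tv$edges[-1] + tv$edges[-length(tv$edges)]) / 2
    jump <- mids[which.max(diff(c(0, tv$cum)))]
    if (abs(jump - cc) <= 0.05 * diff(range(x))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("informative predictors outrank pure noise", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    n <- 120
    x <- runif(n)
    mt <- data.frame(site_id = sprintf("s%03d", 1:n), lat = 0, lon = 0,
                     signal = x, noise = runif(n))
    f <- matrix(plogis(6 * (x - 0.5)) + rnorm(n, sd = 0.05), n)
    f <- matrix(pmin(1, pmax(0, f)), n, dimnames = list(mt$site_id, "snp1"))
    fit <- gf_fit(f, mt, n_trees = 100L, seed = s)
    if (fit$importance["signal"] > fit$importance["noise"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("constant SNPs and constant predictors contribute nothing", {
  ds <- tiny_dataset()
  preds <- c("onset_day", "precip_total_90", "srad_mean_90")
  fq <- ds$freqs[, 1:8]
  fit0 <- gf_fit(fq, ds$site_metrics, n_trees = 50L, seed = 5L,
                 predictors = preds)
  # appending a constant SNP leaves every turnover function unchanged
  fq2 <- cbind(fq, snp_const = rep(0.4, nrow(fq)))
  fit1 <- gf_fit(fq2, ds$site_metrics, n_trees = 50L, seed = 5L,
                 predictors = preds)
  expect_equal(fit1$r2[["snp_const"]], 0)
  for (p in preds)
    expect_equal(fit1$turnover[[p]], fit0$turnover[[p]])

  # appending a constant predictor leaves the other turnover functions and
  # every offset unchanged
  mt2 <- ds$site_metrics
  mt2$flat_metric <- 5
  fit2 <- gf_fit(fq, mt2, n_trees = 50L, seed = 5L,
                 predictors = c(preds, "flat_metric"))
  expect_equal(fit2$importance[["flat_metric"]], 0)
  for (p in preds)
    expect_equal(fit2$turnover[[p]], fit0$turnover[[p]])
  x1 <- ds$site_metrics[3, ]
  x2 <- ds$site_metrics[40, ]
  x1$flat_metric <- 5
  x2$flat_metric <- 5
  expect_equal(genomic_offset(fit2, x1, x2), genomic_offset(fit0, x1, x2))
})

test_that("fraction of predictable SNPs reflects signal content", {
  ds <- tiny_dataset()
  fit <- tiny_fit()
  fp <- fraction_predicted(fit)
  expect_identical(fp$n_total, ncol(ds$freqs))
  expect_identical(fp$n_predictive, sum(fit$r2 > 0))
  expect_lt(fp$fraction, 1)

  # noiseless monotone SNPs are all predictable
  set.seed(2)
  n <- 80
  x <- sort(runif(n, 0, 10))
  mt <- data.frame(site_id = sprintf("s%03d", 1:n), lat = 0, lon = 0,
                   metric_x = x)
  f <- sapply(seq(2, 8, length.out = 5),
              function(cc) as.numeric(x > cc))
  dimnames(f) <- list(mt$site_id, paste0("snp", 1:5))
  fit1 <- gf_fit(f, mt, n_trees = 100L, seed = 3L)
  expect_equal(fraction_predicted(fit1)$fraction, 1)
})

test_that("out-of-bag R2 agrees with an independent random forest", {
  skip_if_not_installed("randomForest")
  ds <- tiny_dataset()
  preds <- c("onset_day", "precip_total_90", "tmean_mean_90", "srad_mean_90")
  fit <- gf_fit(ds$freqs, ds$site_metrics, n_trees = 200L, seed = 9L,
                predictors = preds)
  X <- as.data.frame(ds$site_metrics[match(rownames(ds$freqs),
                                           ds$site_metrics$site_id), preds])
  set.seed(9)
  r2_ref <- apply(ds$freqs, 2, function(y) {
    rf <- randomForest::randomForest(X, y, ntree = 200)
    max(0, tail(rf$rsq, 1))
  })
  expect_gt(cor(fit$r2, r2_ref, method = "spearman"), 0.7)
  expect_lt(mean(abs(fit$r2 - r2_ref)), 0.1)
})

test_that("models survive a JSON round trip", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".json")
  gf_save(fit, path)
  back <- gf_load(path)
  expect_identical(back$predictors, fit$predictors)
  expect_equal(back$r2, fit$r2, tolerance = 1e-12)
  expect_equal(back$importance, fit$importance, tolerance = 1e-12)
  x <- fit$ranges["lo", ] + 0.3 * (fit$ranges["hi", ] - fit$ranges["lo", ])
  names(x) <- fit$predictors
  expect_equal(gf_transform(back, x), gf_transform(fit, x),
               tolerance = 1e-12)
})

test_that("fits are deterministic under a fixed seed", {
  ds <- tiny_dataset()
  preds <- c("onset_day", "srad_mean_90")
  f1 <- gf_fit(ds$freqs[, 1:6], ds$site_metrics, n_trees = 30L, seed = 21L,
               predictors = preds)
  f2 <- gf_fit(ds$freqs[, 1:6], ds$site_metrics, n_trees = 30L, seed = 21L,
               predictors = preds)
  expect_identical(f1$r2, f2$r2)
  expect_identical(f1$turnover, f2$turnover)
})
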