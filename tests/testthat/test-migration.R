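test_that("great-circle distances match the spherical reference", {
  expect_equal(geodesic_km(12, 3, 12, 3), 0)
  expect_equal(geodesic_km(0, 0, 0, 1), 111.195, tolerance = 1e-4)
  set.seed(4)
  la <- runif(100, -60, 60); lo <- runif(100, -180, 180)
  lb <- runif(100, -60, 60); lo2 <- runif(100, -180, 180)
  expect_equal(geodesic_km(la, lo, lb, lo2), geodesic_km(lb, lo2, la, lo))
  expect_error(geodesic_km(91, 0, 0, 0), "latitude")
})

test_that("distances agree with geosphere's haversine", {
  skip_if_not_installed("geosphere")
  set.seed(8)
  a <- cbind(runif(50, -180, 180), runif(50, -85, 85))  # lon, lat
  b <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  ref <- geosphere::distHaversine(a, b, r = 6371008.8) / 1000
  expect_equal(geodesic_km(a[, 2], a[, 1], b[, 2], b[, 1]), ref,
               tolerance = 1e-9)
})

test_that("density clustering matches the neighborhood-expansion oracle", {
  # single blob of 6 pixels all mutually within eps
  off <- data.frame(pixel_id = sprintf("p%02d", 1:20),
                    lat = c(rep(10, 6) + runif(6, 0, 0.2),
                            seq(30, 43, length.out = 14)),
                    lon = c(rep(0, 6) + runif(6, 0, 0.2),
                            seq(30, 43, length.out = 14)),
                    offset = c(rep(5, 6), rep(0.01, 14)))
  cl <- vulnerable_clusters(off, q = 0.5, min_pts = 4, eps_km = 100)
  expect_identical(sort(cl$pixel_id), sprintf("p%02d", 1:6))
  expect_identical(unique(cl$cluster), 1L)

  # three isolated vulnerable pixels are noise
  off2 <- data.frame(pixel_id = sprintf("q%02d", 1:12),
                     lat = c(0, 20, 40, rep(60, 9)),
                     lon = c(0, 20, 40, seq(0, 80, by = 10)),
                     offset = c(5, 5, 5, rep(0.01, 9)))
  cl2 <- vulnerable_clusters(off2, q = 0.7, min_pts = 4, eps_km = 100)
  expect_identical(nrow(cl2), 0L)

  # random instances against the brute-force oracle
  set.seed(11)
  for (i in 1:8) {
    n <- 25
    lat <- runif(n, 5, 15)
    lon <- runif(n, -5, 5)
    dm <- gfoffset:::geodesic_matrix(lat, lon)
    eps <- runif(1, 80, 250)
    labs <- gfoffset:::dbscan_labels(dm, eps, 4)
    expect_true(same_partition(labs, oracle_dbscan(dm, eps, 4)))
  }
  expect_error(vulnerable_clusters(off, eps_km = 0), "eps_km")
})

test_that("cluster labels are invariant under pixel permutation", {
  set.seed(13)
  n <- 30
  lat <- runif(n, 5, 15); lon <- runif(n, -5, 5)
  dm <- gfoffset:::geodesic_matrix(lat, lon)
  labs <- gfoffset:::dbscan_labels(dm, 150, 4)
  perm <- sample(n)
  labs_p <- gfoffset:::dbscan_labels(dm[perm, perm], 150, 4)
  expect_true(same_partition(labs[perm], labs_p))
})

test_that("focal pixel is the offset argmax with lexicographic ties", {
  cl <- data.frame(pixel_id = c("a", "b", "c"), lat = c(3, 2, 1),
                   lon = c(1, 1, 1), offset = c(0.1, 0.5, 0.3))
  expect_identical(focal_pixel(cl)$pixel_id, "b")
  cl$offset <- 0.5
  expect_identical(focal_pixel(cl)$pixel_id, "c")  # smallest (lat, lon)
  expect_identical(focal_pixel(cl[2, ])$pixel_id, "b")
})

test_that("donor choice per strategy matches the exhaustive oracle", {
  set.seed(17)
  n <- 30
  cand <- data.frame(site_id = sprintf("c%02d", 1:n),
                     lat = runif(n, 8, 16), lon = runif(n, -8, 2))
  cand$p1 <- runif(n)
  model <- stub_model(list(p1 = 1))
  focal <- data.frame(pixel_id = "c05", lat = cand$lat[5], lon = cand$lon[5])
  fut <- c(p1 = 0.42)

  tf <- gf_transform(model, fut)
  ed <- apply(gf_transform(model, cand), 1, function(r) sqrt(sum((r - tf)^2)))
  gd <- geodesic_km(focal$lat, focal$lon, cand$lat, cand$lon)

  opt <- donor_search(model, focal, fut, cand, "optimal")
  expect_identical(opt$donor_pixel,
                   cand$site_id[order(ed, gd, cand$lat, cand$lon)[1]])
  expect_equal(opt$load, min(ed))
  expect_true(all(ed >= opt$load))

  for (st in c("near_optimal", "sub_optimal")) {
    qq <- c(near_optimal = 0.01, sub_optimal = 0.05)[[st]]
    m <- max(1, ceiling(n * qq))
    pool <- order(ed, gd, cand$lat, cand$lon)[1:m]
    want <- pool[order(gd[pool], cand$lat[pool], cand$lon[pool])[1]]
    got <- donor_search(model, focal, fut, cand, st)
    expect_identical(got$donor_pixel, cand$site_id[want])
    expect_equal(got$load, ed[want])
    expect_equal(got$distance_km, unname(gd[want]))
  }
})

test_that("self-donation occurs when the focal future matches its present", {
  cand <- data.frame(site_id = c("a", "b", "c"), lat = c(1, 2, 3),
                     lon = c(1, 2, 3), p1 = c(0.6, 0.2, 0.9))
  model <- stub_model(list(p1 = 1))
  focal <- data.frame(pixel_id = "a", lat = 1, lon = 1)
  res <- donor_search(model, focal, c(p1 = 0.6), cand, "optimal")
  expect_identical(res$donor_pixel, "a")
  expect_equal(res$distance_km, 0)
  expect_equal(res$load, 0)
})

test_that("strategy orderings follow from candidate-pool nesting", {
  set.seed(19)
  n <- 200
  cand <- data.frame(site_id = sprintf("c%03d", 1:n),
                     lat = runif(n, 8, 16), lon = runif(n, -8, 2),
                     p1 = runif(n))
  model <- stub_model(list(p1 = 1))
  for (i in 1:5) {
    f <- sample(n, 1)
    focal <- data.frame(pixel_id = cand$site_id[f], lat = cand$lat[f],
                        lon = cand$lon[f])
    fut <- c(p1 = runif(1))
    opt <- donor_search(model, focal, fut, cand, "optimal")
    near <- donor_search(model, focal, fut, cand, "near_optimal")
    sub <- donor_search(model, focal, fut, cand, "sub_optimal")
    expect_lte(sub$distance_km, near$distance_km)
    expect_lte(near$distance_km, opt$distance_km)
    expect_lte(opt$load, near$load)
    expect_lte(opt$load, sub$load)
  }
})

test_that("migration summaries pool plans as plain arithmetic", {
  one <- data.frame(strategy = "optimal", distance_km = 120, load = 0.02,
                    transboundary = TRUE)
  s1 <- summarize_migrations(one)
  expect_equal(s1$dist_mean, 120)
  expect_equal(s1$dist_sd, 0)
  expect_equal(s1$transboundary_pct, 100)

  four <- data.frame(strategy = rep(c("optimal", "sub_optimal"), each = 2),
                     distance_km = c(100, 300, 50, 70),
                     load = c(0.01, 0.03, 0.02, 0.06),
                     transboundary = c(TRUE, FALSE, FALSE, FALSE))
  s4 <- summarize_migrations(four)
  opt <- s4[s4$strategy == "optimal", ]
  expect_equal(opt$n_areas, 2)
  expect_equal(opt$dist_mean, 200)
  expect_equal(opt$dist_sd, sd(c(100, 300)))
  expect_equal(opt$dist_min, 100)
  expect_equal(opt$dist_max, 300)
  expect_equal(opt$transboundary_pct, 50)
  expect_equal(opt$load_mean, 0.02)
  sub <- s4[s4$strategy == "sub_optimal", ]
  expect_equal(sub$dist_mean, 60)
  expect_equal(sub$transboundary_pct, 0)
})
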