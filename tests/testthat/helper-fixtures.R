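# Shared fixtures (computed once per test run) and independent brute-force
# oracles used by the DERIVED-value tests.

.fixtures <- new.env(parent = emptyenv())

tiny_scenario <- function(seed = 3L, ...) {
  args <- list(lat_range = c(10, 14), lon_range = c(-5, 0),
               n_landraces = 60L, n_adaptive_snps = 5L,
               n_neutral_snps = 20L, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_scenario, args)
}

# small end-to-end dataset + turnover fit, shared across test files
tiny_dataset <- function() {
  if (is.null(.fixtures$ds)) .fixtures$ds <- generate_dataset(tiny_scenario())
  .fixtures$ds
}

tiny_fit <- function() {
  if (is.null(.fixtures$fit)) {
    ds <- tiny_dataset()
    keep <- select_uncorrelated(ds$site_metrics)
    .fixtures$fit <- gf_fit(ds$freqs, ds$site_metrics, n_trees = 100L,
                            seed = 11L, predictors = keep)
  }
  .fixtures$fit
}

# hand-buildable turnover model: one-bin step functions with chosen total
# mass per predictor, for analytic offset checks
stub_model <- function(masses, lo = 0, hi = 1) {
  p <- names(masses)
  turnover <- lapply(masses, function(m)
    list(edges = c(lo, (lo + hi) / 2, hi), cum = c(m / 2, m)))
  ranges <- rbind(lo = rep(lo, length(p)), hi = rep(hi, length(p)))
  colnames(ranges) <- p
  structure(list(predictors = p, turnover = turnover, ranges = ranges,
                 r2 = c(snp1 = 1), importance = unlist(masses),
                 n_trees = 1L, mtry = 1L, min_node = 5L, bins = 2L,
                 seed = 1L, n_sites = 2L),
            class = "turnover_model")
}

# --- independent oracles ----------------------------------------------------

# day-by-day scan implementing the onset rule directly
oracle_onset <- function(p, wet_mm = 20, wet_days = 3, dry_thresh = 1,
                         dry_len = 7, dry_win = 20, start = 0) {
  n <- length(p)
  for (d in start:(n - wet_days)) {
    if (sum(p[(d + 1):(d + wet_days)]) < wet_mm) next
    lo <- d + wet_days
    hi <- min(d + wet_days + dry_win - 1, n - 1)
    ok <- TRUE
    run <- 0
    if (lo <= hi) {
      for (j in lo:hi) {
        if (p[j + 1] < dry_thresh) {
          run <- run + 1
          if (run >= dry_len) { ok <- FALSE; break }
        } else run <- 0
      }
    }
    if (ok) return(as.integer(d))
  }
  NA_integer_
}

# set-expansion DBSCAN on a distance matrix
oracle_dbscan <- function(d, eps, minpts) {
  n <- nrow(d)
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= minpts,
                 logical(1))
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    set <- i
    repeat {
      reach <- unique(unlist(lapply(set[core[set]],
                                    function(j) which(d[j, ] <= eps))))
      reach <- reach[lab[reach] == 0L]
      grown <- union(set, reach)
      if (length(grown) == length(set)) break
      set <- grown
    }
    lab[set] <- cl
  }
  lab
}

# identical partitions up to relabeling
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (any((a == 0) != (b == 0))) return(FALSE)
  ok <- a != 0
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# greedy decorrelation re-checked pair by pair
oracle_greedy_cor <- function(x, r_max) {
  kept <- character(0)
  for (m in colnames(x)) {
    ok <- TRUE
    for (k in kept)
      if (abs(stats::cor(x[, m], x[, k])) > r_max) { ok <- FALSE; break }
    if (ok) kept <- c(kept, m)
  }
  kept
}

# Benjamini-Hochberg by explicit step-up thresholds
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * alpha / m)
  sel <- logical(m)
  if (length(k)) sel[o[seq_len(max(k))]] <- TRUE
  sel
}
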