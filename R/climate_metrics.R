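#' Monsoon onset rule parameters
#'
#' The onset of the rainy season anchors every growing-season window. The
#' default is the standard Sahelian agronomic sowing rule: the first day on
#' which at least `wet_mm` mm fall within `wet_days` consecutive days, not
#' followed by a dry spell of `dry_spell_len` or more consecutive days each
#' below `dry_thresh_mm` mm within the next `dry_window` days. All five
#' constants are configurable because published onset definitions differ in
#' detail.
#'
#' @param wet_mm cumulative rainfall threshold (mm) over the wet trigger.
#' @param wet_days length (days) of the wet trigger window.
#' @param dry_thresh_mm a day is dry when rainfall is strictly below this (mm).
#' @param dry_spell_len minimum length (days) of a disqualifying dry spell.
#' @param dry_window number of days after the wet trigger scanned for dry
#'   spells.
#' @param search_start first 0-based day index considered as onset.
#' @return list of class `onset_rule`.
#' @export
onset_rule <- function(wet_mm = 20, wet_days = 3L, dry_thresh_mm = 1,
                       dry_spell_len = 7L, dry_window = 20L,
                       search_start = 0L) {
  stopifnot(wet_mm > 0, wet_days >= 1, dry_thresh_mm >= 0,
            dry_spell_len >= 1, dry_window >= 0, search_start >= 0)
  structure(list(wet_mm = wet_mm, wet_days = as.integer(wet_days),
                 dry_thresh_mm = dry_thresh_mm,
                 dry_spell_len = as.integer(dry_spell_len),
                 dry_window = as.integer(dry_window),
                 search_start = as.integer(search_start)),
            class = "onset_rule")
}

#' Detect monsoon onset in a daily rainfall series
#'
#' Returns the first 0-based day index satisfying the onset rule, or `NA`
#' when no day qualifies (e.g. an all-dry year). Dry spells are scanned in
#' the `dry_window` days immediately following the wet trigger window; a
#' window truncated by the end of the series is scanned as far as data
#' exist.
#'
#' @param precip numeric vector of daily rainfall (mm/day), length >= 210.
#' @param rule an [onset_rule()].
#' @return integer day index (0-based) or `NA_integer_`.
#' @export
detect_monsoon_onset <- function(precip, rule = onset_rule()) {
  if (any(is.na(precip))) stop("missing values in precipitation series")
  if (any(precip < 0)) stop("negative precipitation")
  n <- length(precip)
  if (n < 210L) stop("series too short: need >= 210 days")
  wd <- rule$wet_days
  # rolling sum over the wet trigger window
  cs <- cumsum(c(0, precip))
  last_cand <- n - wd  # 0-based index of last full trigger window
  if (rule$search_start > last_cand) return(NA_integer_)
  dry <- precip < rule$dry_thresh_mm
  for (d in rule$search_start:last_cand) {
    if (cs[d + wd + 1L] - cs[d + 1L] < rule$wet_mm) next
    lo <- d + wd                       # first day after the trigger, 0-based
    hi <- min(d + wd + rule$dry_window - 1L, n - 1L)
    if (lo > hi || !has_dry_spell(dry[(lo + 1L):(hi + 1L)], rule$dry_spell_len))
      return(as.integer(d))
  }
  NA_integer_
}

# TRUE when `dry` (logical) contains a run of >= len consecutive TRUEs
has_dry_spell <- function(dry, len) {
  r <- rle(dry)
  any(r$values & r$lengths >= len)
}

#' The windowed agro-climate metric registry
#'
#' Defines the 26 base metrics computed inside each post-onset window, across
#' the five variable families: 10 precipitation metrics and 4 each for mean,
#' maximum and minimum temperature and shortwave radiation. Together with the
#' six window lengths (30..180 days) and the onset day itself this yields the
#' 157-metric catalog. The registry is data-driven: pass a modified copy to
#' [compute_metrics()] to swap metrics.
#'
#' Event-count thresholds: wet day > 1 mm, heavy-rain day > 20 mm, hot day
#' tmean > 30 / tmax > 35 / tmin > 25 degrees C, low-radiation day
#' < 150 W/m2.
#'
#' @return data.frame with columns `family`, `stat`, `name`.
#' @export
metric_registry <- function() {
  precip_stats <- c("total", "mean", "max_daily", "wet_days", "heavy_days",
                    "max_dry_spell", "max_wet_spell", "sdii", "p95",
                    "dry_days")
  temp_stats <- c("mean", "min", "max", "hot_days")
  srad_stats <- c("mean", "min", "max", "low_days")
  reg <- rbind(
    data.frame(family = "precip", stat = precip_stats),
    data.frame(family = "tmean", stat = temp_stats),
    data.frame(family = "tmax", stat = temp_stats),
    data.frame(family = "tmin", stat = temp_stats),
    data.frame(family = "srad", stat = srad_stats))
  reg$name <- paste(reg$family, reg$stat, sep = "_")
  reg
}

#' Names of the full metric catalog
#' @param windows integer vector of window lengths (days after onset).
#' @param registry base-metric registry, see [metric_registry()].
#' @return character vector: `onset_day` then family_stat_window names.
#' @export
metric_catalog <- function(windows = c(30L, 60L, 90L, 120L, 150L, 180L),
                           registry = metric_registry()) {
  c("onset_day",
    as.vector(t(outer(windows, registry$name,
                      function(w, n) paste(n, w, sep = "_")))))
}

# one base metric on the day slice of a single window
base_metric_value <- function(stat, family, precip, tmean, tmax, tmin, srad) {
  if (family == "precip") {
    wet <- precip > 1
    switch(stat,
      total = sum(precip),
      mean = mean(precip),
      max_daily = max(precip),
      wet_days = sum(wet),
      heavy_days = sum(precip > 20),
      max_dry_spell = max_run(!wet),
      max_wet_spell = max_run(wet),
      sdii = if (any(wet)) sum(precip[wet]) / sum(wet) else 0,
      p95 = as.numeric(stats::quantile(precip, 0.95, names = FALSE)),
      dry_days = sum(!wet),
      stop("unknown precip stat: ", stat))
  } else {
    x <- switch(family, tmean = tmean, tmax = tmax, tmin = tmin, srad = srad,
                stop("unknown family: ", family))
    switch(stat,
      mean = mean(x),
      min = min(x),
      max = max(x),
      hot_days = sum(x > c(tmean = 30, tmax = 35, tmin = 25)[[family]]),
      low_days = sum(x < 150),
      stop("unknown stat: ", stat))
  }
}

max_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Compute the windowed climate metric catalog for every pixel
#'
#' For each pixel, the monsoon onset is detected (or taken from `onset`) and
#' the 26 base metrics are evaluated on each half-open window
#' `[onset, onset + W)` for `W` in `windows`. Pixels whose onset is missing
#' are dropped with a warning. A window that extends past the end of the
#' daily series is an error naming the pixel.
#'
#' @param grid a [daily_climate_grid()].
#' @param onset optional integer vector of 0-based onset days per pixel;
#'   detected with `rule` when `NULL`.
#' @param rule an [onset_rule()].
#' @param windows window lengths in days after onset.
#' @param registry base-metric registry.
#' @return `climate_metric_table`: data.frame with `site_id`, `lat`, `lon`
#'   and one column per catalog metric (157 with the defaults).
#' @export
compute_metrics <- function(grid, onset = NULL, rule = onset_rule(),
                            windows = c(30L, 60L, 90L, 120L, 150L, 180L),
                            registry = metric_registry()) {
  stopifnot(inherits(grid, "daily_climate_grid"))
  np <- nrow(grid$pixels)
  if (is.null(onset)) {
    onset <- vapply(seq_len(np),
                    function(i) detect_monsoon_onset(grid$precip[i, ], rule),
                    integer(1))
  }
  stopifnot(length(onset) == np)
  keep <- !is.na(onset)
  if (!all(keep))
    warning(sprintf("dropping %d pixel(s) with missing monsoon onset",
                    sum(!keep)))
  idx <- which(keep)
  nd <- n_days(grid)
  wmax <- max(windows)
  bad <- idx[onset[idx] + wmax > nd]
  if (length(bad))
    stop(sprintf("window of %d days past series end for pixel %s (onset %d)",
                 wmax, grid$pixels$pixel_id[bad[1]], onset[bad[1]]))
  cat_names <- metric_catalog(windows, registry)
  out <- matrix(NA_real_, nrow = length(idx), ncol = length(cat_names),
                dimnames = list(NULL, cat_names))
  for (r in seq_along(idx)) {
    i <- idx[r]
    o <- onset[i]
    out[r, "onset_day"] <- o
    col <- 1L
    for (w in windows) {
      days <- (o + 1L):(o + w)  # 1-based slice of half-open [onset, onset+w)
      pr <- grid$precip[i, days]; tm <- grid$tmean[i, days]
      tx <- grid$tmax[i, days]; tn <- grid$tmin[i, days]
      sr <- grid$srad[i, days]
      for (k in seq_len(nrow(registry))) {
        col <- col + 1L
        out[r, col] <- base_metric_value(registry$stat[k], registry$family[k],
                                         pr, tm, tx, tn, sr)
      }
    }
  }
  stopifnot(all(is.finite(out)))
  res <- cbind(grid$pixels[idx, c("pixel_id", "lat", "lon")],
               as.data.frame(out))
  names(res)[1] <- "site_id"
  rownames(res) <- NULL
  class(res) <- c("climate_metric_table", "data.frame")
  attr(res, "windows") <- windows
  res
}

#' Metric columns of a climate metric table
#' @param metrics a `climate_metric_table` (or any data.frame with the
#'   site_id/lat/lon prefix columns).
#' @return character vector of metric column names.
#' @export
metric_columns <- function(metrics) {
  setdiff(names(metrics), c("site_id", "lat", "lon"))
}

#' Greedy decorrelation filter on the metric catalog
#'
#' Walks the metrics in a fixed order (by default catalog order; supply
#' `order` — e.g. a fitted model's importance ranking — to prioritise) and
#' keeps a metric iff its absolute Pearson correlation with every metric
#' already kept is at most `r_max`. Zero-variance metrics are excluded with a
#' warning since their correlation is undefined.
#'
#' @param metrics a `climate_metric_table`.
#' @param r_max maximum tolerated absolute pairwise Pearson correlation.
#' @param order optional character vector of metric names giving the greedy
#'   visiting order (metrics absent from `order` are appended in catalog
#'   order).
#' @return character vector of kept metric names, in visiting order.
#' @export
select_uncorrelated <- function(metrics, r_max = 0.7, order = NULL) {
  cols <- metric_columns(metrics)
  x <- as.matrix(metrics[, cols, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 sites to estimate correlations")
  if (!is.null(order)) {
    order <- intersect(order, cols)
    cols <- c(order, setdiff(cols, order))
  }
  sds <- apply(x, 2, stats::sd)
  degenerate <- cols[sds[cols] == 0]
  if (length(degenerate)) {
    warning("excluding zero-variance metric(s): ",
            paste(degenerate, collapse = ", "))
    cols <- setdiff(cols, degenerate)
  }
  kept <- character(0)
  for (m in cols) {
    if (!length(kept)) { kept <- m; next }
    r <- abs(stats::cor(x[, m], x[, kept, drop = FALSE]))
    if (all(r <= r_max)) kept <- c(kept, m)
  }
  kept
}
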