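#' Synthetic study scenario
#'
#' Bundles every knob of the seeded synthetic-data generator. The defaults
#' emulate the structure of a West African pearl millet landrace panel on a
#' 0.5-degree grid: a latitudinal monsoon gradient (onset later further
#' north), allele-frequency clines driven by a designated climate metric,
#' neutral background SNPs, bimodal flowering time and yield declining with
#' climate mismatch from a common-garden site.
#'
#' @param lat_range,lon_range numeric length-2, degrees; non-degenerate.
#' @param resolution pixel size in degrees (> 0).
#' @param n_landraces number of landraces to place (>= 2).
#' @param n_adaptive_snps,n_neutral_snps SNP counts (sum >= 1).
#' @param cline_steepness logistic slope of adaptive clines on the
#'   standardized driver metric (dimensionless, > 0; 0 allowed to simulate
#'   the no-adaptation null).
#' @param noise_sd SD of truncated-Gaussian frequency noise (frequency
#'   units, >= 0).
#' @param onset_shift_days future perturbation: monsoon delayed by this many
#'   days.
#' @param precip_scale future perturbation: precipitation multiplied by this.
#' @param warming_c future perturbation: uniform temperature offset (deg C).
#' @param n_countries number of longitudinal country bands (>= 1).
#' @param seed integer master seed; identical seed + parameters give
#'   bit-identical outputs.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(lat_range = c(9, 16), lon_range = c(-12, 3),
                               resolution = 0.5, n_landraces = 173L,
                               n_adaptive_snps = 20L, n_neutral_snps = 180L,
                               cline_steepness = 4, noise_sd = 0.05,
                               onset_shift_days = 10L, precip_scale = 0.9,
                               warming_c = 2, n_countries = 10L,
                               seed = 1L) {
  stopifnot(resolution > 0,
            diff(lat_range) > 0, diff(lon_range) > 0,
            n_adaptive_snps + n_neutral_snps >= 1,
            cline_steepness >= 0, noise_sd >= 0, precip_scale >= 0,
            n_countries >= 1, n_landraces >= 2)
  structure(list(
    lat_range = lat_range, lon_range = lon_range, resolution = resolution,
    n_landraces = as.integer(n_landraces),
    n_adaptive_snps = as.integer(n_adaptive_snps),
    n_neutral_snps = as.integer(n_neutral_snps),
    cline_steepness = cline_steepness, noise_sd = noise_sd,
    onset_shift_days = as.integer(onset_shift_days),
    precip_scale = precip_scale, warming_c = warming_c,
    n_countries = as.integer(n_countries), seed = as.integer(seed)),
    class = "synthetic_scenario")
}

grid_centers <- function(scenario) {
  res <- scenario$resolution
  lat <- seq(scenario$lat_range[1] + res / 2, scenario$lat_range[2], by = res)
  lat <- lat[lat <= scenario$lat_range[2]]
  lon <- seq(scenario$lon_range[1] + res / 2, scenario$lon_range[2], by = res)
  lon <- lon[lon <= scenario$lon_range[2]]
  if (!length(lat) || !length(lon)) stop("degenerate grid: 0 pixels")
  g <- expand.grid(lon = lon, lat = lat)
  data.frame(pixel_id = sprintf("px%04d", seq_len(nrow(g))),
             lat = g$lat, lon = g$lon)
}

#' Generate current and future daily climate grids
#'
#' Synthesises a 365-day monsoonal climate year per pixel: a wet season whose
#' start day increases linearly with latitude (about 5 days per degree, i.e.
#' monsoon arriving later further north), rainfall as Bernoulli wet days with
#' a sine-envelope intensity, a seasonal temperature cycle and shortwave
#' radiation dipping during the cloudy monsoon. The future grid is a
#' deterministic transform of the current one: precipitation shifted later by
#' `onset_shift_days` (zero-filled head) and scaled by `precip_scale`,
#' temperatures offset by `warming_c`. With a zero perturbation the future
#' grid is identical to the current grid.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with elements `current` and `future`, both
#'   [daily_climate_grid()]s.
#' @export
generate_climate <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  px <- grid_centers(scenario)
  np <- nrow(px)
  nd <- 365L
  days <- 0:(nd - 1L)
  season_len <- 140
  onset_true <- 95 + 5 * (px$lat - scenario$lat_range[1])

  precip <- matrix(0, np, nd)
  tmean <- matrix(0, np, nd)
  srad <- matrix(0, np, nd)
  for (i in seq_len(np)) {
    u <- (days - onset_true[i]) / season_len
    env <- ifelse(u > 0 & u < 1, sin(pi * u)^0.5, 0)
    p_wet <- ifelse(env > 0, 0.35 + 0.55 * env, 0.02)
    mean_mm <- ifelse(env > 0, 5 + 13 * env, 3)
    wet <- stats::rbinom(nd, 1L, p_wet) == 1L
    precip[i, wet] <- stats::rexp(sum(wet), rate = 1 / mean_mm[wet])
    tmean[i, ] <- 28 + 0.4 * (px$lat[i] - scenario$lat_range[1]) +
      3 * cos(2 * pi * (days - 105) / 365) - 2.5 * env +
      stats::rnorm(nd, sd = 0.6)
    srad[i, ] <- pmax(60, 255 + 15 * cos(2 * pi * (days - 40) / 365) -
                        90 * env + stats::rnorm(nd, sd = 8))
  }
  current <- daily_climate_grid(px, precip, tmean, tmean + 6, tmean - 6,
                                srad, period = "current", model = "synthetic",
                                scenario = "historical")
  future <- perturb_climate(current, scenario$onset_shift_days,
                            scenario$precip_scale, scenario$warming_c)
  list(current = current, future = future)
}

#' Apply a future perturbation to a climate grid
#'
#' @param grid a [daily_climate_grid()].
#' @param onset_shift_days delay (days, >= 0) applied to the precipitation
#'   series (head zero-filled).
#' @param precip_scale multiplier on precipitation.
#' @param warming_c additive temperature offset (deg C), applied to tmean,
#'   tmax and tmin alike.
#' @return a `daily_climate_grid` labelled as a future period.
#' @export
perturb_climate <- function(grid, onset_shift_days = 0L, precip_scale = 1,
                            warming_c = 0) {
  stopifnot(onset_shift_days >= 0, precip_scale >= 0)
  k <- as.integer(onset_shift_days)
  nd <- n_days(grid)
  pr <- grid$precip
  if (k > 0) {
    pr <- cbind(matrix(0, nrow(pr), k), pr[, 1:(nd - k), drop = FALSE])
  }
  daily_climate_grid(grid$pixels, pr * precip_scale,
                     grid$tmean + warming_c, grid$tmax + warming_c,
                     grid$tmin + warming_c, grid$srad,
                     period = "future", model = grid$model,
                     scenario = grid$scenario)
}

#' Place synthetic landraces on the grid
#'
#' Landraces are placed uniformly over the grid extent, assigned to their
#' containing pixel, and labelled with a country from a deterministic
#' partition of the longitude span into `n_countries` equal bands.
#'
#' @param scenario a [synthetic_scenario()].
#' @param grid the current [daily_climate_grid()] (supplies the pixel set).
#' @return data.frame with `id`, `lat`, `lon`, `country`, `pixel_id`.
#' @export
generate_landraces <- function(scenario, grid) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(grid, "daily_climate_grid"))
  if (scenario$n_landraces < 2L) stop("need at least 2 landraces")
  set.seed(scenario$seed + 1L)
  n <- scenario$n_landraces
  lat <- stats::runif(n, scenario$lat_range[1], scenario$lat_range[2])
  lon <- stats::runif(n, scenario$lon_range[1], scenario$lon_range[2])
  lr <- data.frame(id = sprintf("LR%03d", seq_len(n)), lat = lat, lon = lon,
                   country = pixel_country(lon, scenario),
                   pixel_id = containing_pixel(lat, lon, grid$pixels,
                                               scenario$resolution))
  lr
}

# country label from a longitudinal band partition
pixel_country <- function(lon, scenario) {
  width <- diff(scenario$lon_range) / scenario$n_countries
  band <- pmin(scenario$n_countries,
               pmax(1L, ceiling((lon - scenario$lon_range[1]) / width)))
  sprintf("country%02d", band)
}

containing_pixel <- function(lat, lon, pixels, resolution) {
  id <- character(length(lat))
  for (i in seq_along(lat)) {
    d <- pmax(abs(pixels$lat - lat[i]), abs(pixels$lon - lon[i]))
    j <- which.min(d)
    if (d[j] > resolution / 2 + 1e-9)
      stop(sprintf("point (%.3f, %.3f) outside the grid", lat[i], lon[i]))
    id[i] <- pixels$pixel_id[j]
  }
  id
}

#' Extract climate metrics at landrace sites
#'
#' Landrace-site climate is taken from the containing pixel (no
#' interpolation). Errors when a landrace's pixel is absent from the metric
#' table.
#'
#' @param metrics a `climate_metric_table` computed on the pixel grid.
#' @param landraces landrace table with `id` and `pixel_id`.
#' @return a `climate_metric_table` with one row per landrace
#'   (`site_id` = landrace id).
#' @export
landrace_metrics <- function(metrics, landraces) {
  i <- match(landraces$pixel_id, metrics$site_id)
  if (anyNA(i))
    stop("metric table missing pixel(s): ",
         paste(unique(landraces$pixel_id[is.na(i)]), collapse = ", "))
  out <- metrics[i, , drop = FALSE]
  out$site_id <- landraces$id
  out$lat <- landraces$lat
  out$lon <- landraces$lon
  rownames(out) <- NULL
  out
}

#' Generate clinal allele frequencies plus ground truth
#'
#' Each adaptive SNP follows a logistic cline on the standardized driver
#' metric: expected frequency `plogis(steepness * (z - c))` with a
#' SNP-specific threshold `c` drawn uniformly in \[-1, 1\]. Neutral SNPs get
#' a site-independent Beta(2, 2) base frequency. Truncated-Gaussian noise
#' (`noise_sd`) is added and frequencies clipped to \[0, 1\].
#'
#' @param scenario a [synthetic_scenario()].
#' @param landraces landrace table.
#' @param metrics `climate_metric_table` at landrace sites (see
#'   [landrace_metrics()]).
#' @param driver name of the metric driving adaptive clines.
#' @return list with `freqs` (landraces x SNPs matrix, rownames = landrace
#'   ids) and `truth` (adaptive SNP ids, driver, thresholds, standardized
#'   driver values).
#' @export
generate_allele_freqs <- function(scenario, landraces, metrics,
                                  driver = "onset_day") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!all(landraces$id %in% metrics$site_id))
    stop("metric table missing landrace site(s): ",
         paste(setdiff(landraces$id, metrics$site_id), collapse = ", "))
  set.seed(scenario$seed + 2L)
  m <- metrics[match(landraces$id, metrics$site_id), , drop = FALSE]
  zraw <- m[[driver]]
  z <- as.numeric(scale(zraw))
  n <- nrow(landraces)
  na <- scenario$n_adaptive_snps
  nn <- scenario$n_neutral_snps
  freqs <- matrix(NA_real_, n, na + nn)
  cj <- if (na > 0) stats::runif(na, -1, 1) else numeric(0)
  for (j in seq_len(na))
    freqs[, j] <- stats::plogis(scenario$cline_steepness * (z - cj[j]))
  if (nn > 0) {
    base <- stats::rbeta(nn, 2, 2)
    freqs[, na + seq_len(nn)] <- matrix(base, n, nn, byrow = TRUE)
  }
  freqs <- freqs + stats::rnorm(length(freqs), sd = scenario$noise_sd)
  freqs <- matrix(pmin(1, pmax(0, freqs)), nrow = n)
  snp_ids <- c(if (na > 0) sprintf("snp_adapt_%03d", seq_len(na)),
               if (nn > 0) sprintf("snp_neut_%03d", seq_len(nn)))
  dimnames(freqs) <- list(landraces$id, snp_ids)
  truth <- list(adaptive = snp_ids[seq_len(na)], driver = driver,
                thresholds = stats::setNames(cj, snp_ids[seq_len(na)]),
                z = stats::setNames(z, landraces$id))
  list(freqs = freqs, truth = truth)
}

#' Generate flowering time and common-garden yield phenotypes
#'
#' Flowering time is `baseline + sum(effect * frequency)` over a causal SNP
#' subset plus Gaussian noise; with the default single causal SNP of effect
#' 50 days on a steep cline the marginal distribution is bimodal with modes
#' near 60 and 110 days. Yield traits (100-seed weight, main-spike seed
#' weight, seeds per plant) decline linearly with the climate mismatch
#' between a landrace's origin and a designated common-garden pixel; seeds
#' per plant is main-spike weight times a productive-tiller count.
#'
#' @param scenario a [synthetic_scenario()].
#' @param landraces landrace table.
#' @param freqs allele-frequency matrix from [generate_allele_freqs()].
#' @param truth ground-truth list from [generate_allele_freqs()].
#' @param metrics `climate_metric_table` at landrace sites.
#' @param garden_site site id of the common-garden location; default is the
#'   landrace site closest to the panel centroid.
#' @param causal ids of causal SNPs for flowering; default the first
#'   adaptive SNP.
#' @param effects flowering effect sizes (days per unit frequency).
#' @param baseline_days,flower_noise_sd flowering model constants.
#' @param yield_noise stochastic noise switch for yield traits.
#' @return data.frame with `id`, `flowering_days`, the three yield traits,
#'   `productive_tillers` and `climate_mismatch` (standardized driver
#'   distance to the garden).
#' @export
generate_phenotypes <- function(scenario, landraces, freqs, truth, metrics,
                                garden_site = NULL, causal = NULL,
                                effects = NULL, baseline_days = 60,
                                flower_noise_sd = 5, yield_noise = TRUE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!all(landraces$id %in% rownames(freqs)))
    stop("frequency matrix missing landrace(s)")
  if (is.null(causal)) {
    if (!length(truth$adaptive)) stop("empty causal SNP subset")
    causal <- truth$adaptive[1]
  }
  if (!length(causal)) stop("empty causal SNP subset")
  if (is.null(effects)) effects <- rep(50, length(causal))
  set.seed(scenario$seed + 3L)
  fq <- freqs[landraces$id, causal, drop = FALSE]
  n <- nrow(landraces)
  flowering <- baseline_days + as.numeric(fq %*% effects) +
    stats::rnorm(n, sd = flower_noise_sd)

  m <- metrics[match(landraces$id, metrics$site_id), , drop = FALSE]
  z <- as.numeric(scale(m[[truth$driver]]))
  if (is.null(garden_site)) {
    cen <- c(mean(landraces$lat), mean(landraces$lon))
    garden_site <- landraces$id[
      which.min((landraces$lat - cen[1])^2 + (landraces$lon - cen[2])^2)]
  }
  zg <- z[match(garden_site, landraces$id)]
  if (is.na(zg)) stop("garden site not found among landrace sites")
  mismatch <- abs(z - zg)
  ns <- function(sd) if (yield_noise) stats::rnorm(n, sd = sd) else 0
  seed_weight_100 <- 1.2 - 0.25 * mismatch + ns(0.12)
  spike_weight <- 18 - 3.5 * mismatch + ns(1.6)
  tillers <- pmax(1, 2.5 + ns(0.3))
  data.frame(id = landraces$id,
             flowering_days = flowering,
             seed_weight_100 = seed_weight_100,
             spike_weight = spike_weight,
             seeds_per_plant = spike_weight * tillers,
             productive_tillers = tillers,
             climate_mismatch = mismatch,
             garden_site = garden_site)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining climate, landraces, pixel metrics,
#' landrace-site metrics, allele frequencies and phenotypes for one
#' scenario.
#'
#' @param scenario a [synthetic_scenario()].
#' @param rule an [onset_rule()].
#' @return list: `scenario`, `climate` (current/future grids), `landraces`,
#'   `pixel_metrics` (current), `pixel_metrics_future`, `site_metrics`,
#'   `freqs`, `truth`, `phenotypes`.
#' @export
generate_dataset <- function(scenario = synthetic_scenario(),
                             rule = onset_rule()) {
  climate <- generate_climate(scenario)
  landraces <- generate_landraces(scenario, climate$current)
  pm_cur <- compute_metrics(climate$current, rule = rule)
  pm_fut <- compute_metrics(climate$future, rule = rule)
  site_m <- landrace_metrics(pm_cur, landraces)
  af <- generate_allele_freqs(scenario, landraces, site_m)
  ph <- generate_phenotypes(scenario, landraces, af$freqs, af$truth, site_m)
  list(scenario = scenario, climate = climate, landraces = landraces,
       pixel_metrics = pm_cur, pixel_metrics_future = pm_fut,
       site_metrics = site_m, freqs = af$freqs, truth = af$truth,
       phenotypes = ph)
}
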