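#' Read and write allele-frequency matrices
#'
#' CSV dialect: first column `id` (landrace), remaining columns one per SNP,
#' values in \[0, 1\], complete (no missing cells). Violations are reported
#' with the offending row and column.
#'
#' @param path CSV file.
#' @param freqs landraces x SNPs matrix.
#' @return `read_allele_freqs`: the validated matrix; `write_allele_freqs`:
#'   the path, invisibly.
#' @export
read_allele_freqs <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "id") stop("first column must be 'id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing frequency at row %s, SNP %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("frequency outside [0, 1] at row %s, SNP %s (value %g)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]))
  m
}

#' @rdname read_allele_freqs
#' @export
write_allele_freqs <- function(freqs, path) {
  d <- data.frame(id = rownames(freqs), freqs, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read and write landrace tables
#'
#' CSV with header `id, lat, lon, country` (plus any extra columns, e.g.
#' `pixel_id`). Coordinates are range-checked.
#'
#' @param path CSV file.
#' @param landraces landrace data.frame.
#' @export
read_landraces <- function(path) {
  d <- utils::read.csv(path)
  need <- c("id", "lat", "lon", "country")
  if (!all(need %in% names(d)))
    stop("landrace table must have columns: ", paste(need, collapse = ", "))
  bad <- which(abs(d$lat) > 90 | abs(d$lon) > 180 | is.na(d$lat) |
                 is.na(d$lon))
  if (length(bad))
    stop("invalid coordinates at line ", bad[1] + 1L)
  d
}

#' @rdname read_landraces
#' @export
write_landraces <- function(landraces, path) {
  utils::write.csv(landraces, path, row.names = FALSE)
  invisible(path)
}

#' Read and write daily climate grids as long CSV
#'
#' Dialect: columns `pixel_id, lat, lon, day` (0-based) and the five
#' variables `precip, tmean, tmax, tmin, srad`; one row per pixel-day.
#'
#' @param path CSV file.
#' @param grid a [daily_climate_grid()].
#' @param period,model,scenario labels applied on read.
#' @export
read_climate_csv <- function(path, period = "current", model = "obs",
                             scenario = "historical") {
  d <- utils::read.csv(path)
  need <- c("pixel_id", "lat", "lon", "day", "precip", "tmean", "tmax",
            "tmin", "srad")
  if (!all(need %in% names(d)))
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(match(d$pixel_id, unique(d$pixel_id)), d$day), ]
  px_ids <- unique(d$pixel_id)
  days <- sort(unique(d$day))
  if (!identical(sort(unique(d$day)), seq(0L, max(d$day))))
    stop("day index must be a complete 0-based sequence")
  np <- length(px_ids); nd <- length(days)
  if (nrow(d) != np * nd) stop("climate CSV is not a complete pixel x day grid")
  shape <- function(v) matrix(v, np, nd, byrow = TRUE)
  first <- d[!duplicated(d$pixel_id), c("pixel_id", "lat", "lon")]
  rownames(first) <- NULL
  daily_climate_grid(first, shape(d$precip), shape(d$tmean), shape(d$tmax),
                     shape(d$tmin), shape(d$srad), period, model, scenario)
}

#' @rdname read_climate_csv
#' @export
write_climate_csv <- function(grid, path) {
  np <- nrow(grid$pixels); nd <- n_days(grid)
  d <- data.frame(
    pixel_id = rep(grid$pixels$pixel_id, each = nd),
    lat = rep(grid$pixels$lat, each = nd),
    lon = rep(grid$pixels$lon, each = nd),
    day = rep(0:(nd - 1L), np),
    precip = as.vector(t(grid$precip)),
    tmean = as.vector(t(grid$tmean)),
    tmax = as.vector(t(grid$tmax)),
    tmin = as.vector(t(grid$tmin)),
    srad = as.vector(t(grid$srad)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a metric table with its catalog manifest
#'
#' The wide CSV holds `site_id, lat, lon` plus one column per metric; the
#' JSON manifest names every metric so downstream consumers can verify the
#' catalog.
#'
#' @param metrics a `climate_metric_table`.
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  jsonlite::write_json(
    list(n_metrics = length(metric_columns(metrics)),
         metrics = metric_columns(metrics)),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Migration plans as GeoJSON LineStrings
#'
#' One LineString per plan, from focal to donor pixel, with the plan fields
#' as properties.
#'
#' @param plans a `migration_plan`.
#' @param path output file.
#' @export
write_plans_geojson <- function(plans, path) {
  feats <- lapply(seq_len(nrow(plans)), function(i) {
    p <- plans[i, ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(p$focal_lon, p$focal_lat),
                                            c(p$donor_lon, p$donor_lat))),
         properties = list(model = p$model, cluster = p$cluster,
                           strategy = p$strategy,
                           distance_km = p$distance_km, load = p$load,
                           transboundary = p$transboundary))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Single source of the pipeline's constants: the MAF thresholds (0.10 for
#' the turnover model, 0.05 for association), 500 trees per SNP, FDR 5%,
#' the 10% vulnerability quantile, DBSCAN min_pts 4 and eps, the 1200 km
#' cluster-separation constant and the 1% / 5% donor-pool quantiles.
#' Round-trips losslessly through JSON.
#'
#' @param maf_gf,maf_gwas MAF thresholds.
#' @param n_trees trees per SNP forest.
#' @param K latent factor count (`NULL`: choose from the screeplot).
#' @param fdr_alpha FDR level.
#' @param vuln_q vulnerability quantile.
#' @param min_pts,eps_km,merge_km clustering constants (km).
#' @param strategy_q named donor-pool quantiles.
#' @param use_uncorrelated fit on the decorrelated metric subset
#'   (`r_max = 0.7`) instead of the full catalog.
#' @param n_models number of synthetic ensemble members.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_gf = 0.10, maf_gwas = 0.05, n_trees = 500L,
                            K = NULL, fdr_alpha = 0.05, vuln_q = 0.90,
                            min_pts = 4L, eps_km = 300, merge_km = 1200,
                            strategy_q = c(near_optimal = 0.01,
                                           sub_optimal = 0.05),
                            use_uncorrelated = FALSE, n_models = 3L,
                            seed = 1L) {
  stopifnot(maf_gf > 0, maf_gf < 0.5, maf_gwas > 0, maf_gwas < 0.5,
            n_trees >= 1, fdr_alpha > 0, fdr_alpha < 1,
            vuln_q > 0, vuln_q < 1, min_pts >= 1, eps_km > 0,
            merge_km > 0, all(strategy_q > 0), all(strategy_q <= 1),
            n_models >= 1)
  structure(list(maf_gf = maf_gf, maf_gwas = maf_gwas,
                 n_trees = as.integer(n_trees), K = K,
                 fdr_alpha = fdr_alpha, vuln_q = vuln_q,
                 min_pts = as.integer(min_pts), eps_km = eps_km,
                 merge_km = merge_km, strategy_q = strategy_q,
                 use_uncorrelated = use_uncorrelated,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$strategy_q <- as.list(obj$strategy_q)  # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$strategy_q <- unlist(obj$strategy_q)
  do.call(pipeline_config, obj)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates the whole analysis end to end on one synthetic scenario:
#' observed climate, landraces, allele frequencies and phenotypes; a small
#' ensemble of `n_models` synthetic climate members (differing in weather
#' noise, sharing geometry and landraces); per-member metric tables, MAF
#' filter and turnover-model fits; the multi-model vulnerability map;
#' assisted-migration plans and their pooled summary; flowering-time
#' association and the R2 comparison; and the common-garden yield
#' validation. All outputs are written under `outdir` together with a
#' manifest carrying the seed and a config hash; the run is deterministic
#' for a fixed config and scenario.
#'
#' @param scenario a [synthetic_scenario()] (its `seed` is overridden by
#'   the config seed).
#' @param config a [pipeline_config()].
#' @param outdir output directory (created); `NULL` skips file output.
#' @return list of in-memory artifacts: `dataset`, `fits`, `vmap`, `plans`,
#'   `migration_summary`, `assoc`, `r2_comparison`, `yield_validation`,
#'   `fraction_predicted`, `outdir`.
#' @export
run_pipeline <- function(scenario = synthetic_scenario(),
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(config, "pipeline_config"))
  scenario$seed <- config$seed
  message("stage 1/6: synthetic data")
  ds <- generate_dataset(scenario)
  n_snps <- ncol(ds$freqs)

  message("stage 2/6: climate ensemble + metrics")
  members <- paste0("model", sprintf("%02d", seq_len(config$n_models)))
  cur_m <- list(); fut_m <- list(); site_m <- list()
  for (m in seq_len(config$n_models)) {
    sc <- scenario
    sc$seed <- scenario$seed + 1000L * m
    cl <- if (m == 1) ds$climate else generate_climate(sc)
    cur <- if (m == 1) ds$pixel_metrics else compute_metrics(cl$current)
    fut <- if (m == 1) ds$pixel_metrics_future else
      compute_metrics(cl$future)
    cur_m[[members[m]]] <- cur
    fut_m[[members[m]]] <- fut
    site_m[[members[m]]] <- landrace_metrics(cur, ds$landraces)
  }

  message("stage 3/6: turnover models (", n_snps, " SNPs, ",
          config$n_trees, " trees/SNP, ", config$n_models, " member(s))")
  fq <- filter_maf(ds$freqs, config$maf_gf)
  predictors <- if (config$use_uncorrelated)
    select_uncorrelated(site_m[[1]]) else NULL
  fits <- lapply(seq_len(config$n_models), function(m)
    gf_fit(fq, site_m[[m]], n_trees = config$n_trees,
           seed = config$seed + m, predictors = predictors))
  names(fits) <- members

  message("stage 4/6: vulnerability map")
  vmap <- map_offsets(fits, cur_m, fut_m, ds$landraces)

  message("stage 5/6: migration plans")
  countries <- stats::setNames(
    pixel_country(ds$climate$current$pixels$lon, scenario),
    ds$climate$current$pixels$pixel_id)
  plans <- plan_migrations(vmap, fits, cur_m, fut_m, countries,
                           q = config$vuln_q, min_pts = config$min_pts,
                           eps_km = config$eps_km,
                           min_cluster = config$min_pts,
                           merge_km = config$merge_km)
  mig_sum <- if (nrow(plans)) summarize_migrations(plans) else NULL

  message("stage 6/6: association + yield validation")
  fq_gwas <- filter_maf(ds$freqs, config$maf_gwas)
  K <- if (is.null(config$K)) choose_k(fq_gwas) else as.integer(config$K)
  assoc <- lfmm_fit(fq_gwas, ds$phenotypes$flowering_days, K)
  sel <- fdr_select(assoc$stats$p, config$fdr_alpha)
  obs_fit <- fits[[1]]
  selected_ids <- intersect(assoc$stats$snp[sel$selected], names(obs_fit$r2))
  r2_cmp <- if (length(selected_ids)) compare_r2(obs_fit, selected_ids) else
    NULL

  garden_px <- ds$landraces$pixel_id[
    match(ds$phenotypes$garden_site[1], ds$landraces$id)]
  garden_row <- ds$pixel_metrics[
    match(garden_px, ds$pixel_metrics$site_id), , drop = FALSE]
  vulns <- landrace_site_vulnerability(obs_fit, ds$site_metrics, garden_row)
  yield_val <- correlate_yield(
    vulns, ds$phenotypes[, c("id", "seed_weight_100", "spike_weight",
                             "seeds_per_plant")])

  out <- list(dataset = ds, fits = fits,
              current_metrics = cur_m, future_metrics = fut_m,
              vmap = vmap, plans = plans,
              migration_summary = mig_sum,
              assoc = assoc, fdr = sel, r2_comparison = r2_cmp,
              yield_validation = yield_val,
              fraction_predicted = fraction_predicted(obs_fit),
              outdir = outdir)
  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir)
  out
}

write_pipeline_outputs <- function(out, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- out$dataset
  write_landraces(ds$landraces, file.path(outdir, "landraces.csv"))
  utils::write.csv(ds$phenotypes, file.path(outdir, "phenotypes.csv"),
                   row.names = FALSE)
  write_allele_freqs(ds$freqs, file.path(outdir, "allele_freqs.csv"))
  write_metrics(ds$pixel_metrics, file.path(outdir, "pixel_metrics.csv"))
  utils::write.csv(out$vmap$offsets, file.path(outdir, "offsets.csv"),
                   row.names = FALSE)
  utils::write.csv(out$vmap$summary,
                   file.path(outdir, "vulnerability_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$plans),
                   file.path(outdir, "migration_plans.csv"),
                   row.names = FALSE)
  if (nrow(out$plans))
    write_plans_geojson(out$plans,
                        file.path(outdir, "migration_plans.geojson"))
  utils::write.csv(cbind(out$assoc$stats, q = out$fdr$q,
                         selected = out$fdr$selected),
                   file.path(outdir, "association.csv"), row.names = FALSE)
  utils::write.csv(qq_table(out$assoc$stats$p),
                   file.path(outdir, "qq_table.csv"), row.names = FALSE)
  utils::write.csv(out$yield_validation,
                   file.path(outdir, "yield_validation.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(outdir, "config.json")
  write_config(config, cfg_path)
  summary <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_landraces = nrow(ds$landraces),
    n_snps_total = ncol(ds$freqs),
    n_snps_gf = length(out$fits[[1]]$r2),
    fraction_predicted = out$fraction_predicted$fraction,
    n_pixels_mapped = nrow(out$vmap$summary),
    mean_offset = mean(out$vmap$summary$mean),
    n_plans = nrow(out$plans),
    migration = out$migration_summary,
    K = out$assoc$K,
    n_selected = out$fdr$n_selected,
    r2_comparison = out$r2_comparison,
    yield_validation = out$yield_validation)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(outdir)
}
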