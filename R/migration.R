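#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distance(s) in km.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("invalid latitude")
  if (any(abs(c(lon1, lon2)) > 360)) stop("invalid longitude")
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# full pairwise great-circle distance matrix (km)
geodesic_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- geodesic_km(lat[i], lon[i], lat, lon)
  d
}

# DBSCAN with precomputed distances: core point = >= min_pts neighbours
# (self included) within eps; border points join the first core cluster
# that reaches them; noise labelled 0
dbscan_labels <- function(dist_mat, eps, min_pts) {
  if (eps <= 0) stop("eps_km must be > 0")
  n <- nrow(dist_mat)
  nb <- lapply(seq_len(n), function(i) which(dist_mat[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, setdiff(nb[[j]][labels[nb[[j]]] == 0L], j))
      }
    }
  }
  labels
}

#' Cluster the most vulnerable pixels of one climate model
#'
#' Selects pixels with offset strictly above the `q` quantile of the model's
#' offsets, clusters them with DBSCAN over great-circle distances
#' (`eps_km` neighbourhood, `min_pts` core threshold), discards noise and
#' clusters with fewer than `min_cluster` pixels, and iteratively merges
#' clusters whose most-vulnerable (focal) pixels are closer than `merge_km`,
#' so retained vulnerable areas are well separated.
#'
#' @param offsets data.frame with `pixel_id`, `lat`, `lon`, `offset` for one
#'   climate model.
#' @param q vulnerability quantile (default 0.90: the 10 percent most
#'   vulnerable pixels).
#' @param min_pts DBSCAN core threshold.
#' @param eps_km DBSCAN neighbourhood radius (km).
#' @param min_cluster minimum retained cluster size.
#' @param merge_km clusters with focal pixels closer than this are merged.
#' @return data.frame of vulnerable pixels with a `cluster` column
#'   (retained clusters renumbered 1..k), or 0 rows when none qualify.
#' @export
vulnerable_clusters <- function(offsets, q = 0.90, min_pts = 4L,
                                eps_km = 300, min_cluster = 4L,
                                merge_km = 1200) {
  stopifnot(nrow(offsets) >= 10)
  if (eps_km <= 0) stop("eps_km must be > 0")
  thr <- stats::quantile(offsets$offset, q, names = FALSE)
  vul <- offsets[offsets$offset > thr, , drop = FALSE]
  if (!nrow(vul)) {
    vul$cluster <- integer(0)
    return(vul)
  }
  dm <- geodesic_matrix(vul$lat, vul$lon)
  labels <- dbscan_labels(dm, eps_km, min_pts)
  keep_cl <- as.integer(names(which(table(labels[labels > 0]) >= min_cluster)))
  vul <- vul[labels %in% keep_cl, , drop = FALSE]
  labels <- labels[labels %in% keep_cl]
  if (!nrow(vul)) {
    vul$cluster <- integer(0)
    rownames(vul) <- NULL
    return(vul)
  }
  labels <- match(labels, sort(unique(labels)))
  # merge clusters whose focal pixels are within merge_km of each other
  repeat {
    k <- max(labels)
    if (k < 2) break
    focals <- t(vapply(seq_len(k), function(cl) {
      f <- focal_pixel(vul[labels == cl, , drop = FALSE])
      c(f$lat, f$lon)
    }, numeric(2)))
    fd <- geodesic_matrix(focals[, 1], focals[, 2])
    fd[upper.tri(fd, diag = TRUE)] <- Inf
    if (min(fd) >= merge_km) break
    pair <- which(fd == min(fd), arr.ind = TRUE)[1, ]
    labels[labels == pair["row"]] <- pair["col"]
    labels <- match(labels, sort(unique(labels)))
  }
  vul$cluster <- labels
  rownames(vul) <- NULL
  vul
}

#' Most vulnerable pixel of a cluster
#'
#' Argmax of offset; ties broken by (lat, lon) lexicographic order.
#'
#' @param cluster data.frame with `pixel_id`, `lat`, `lon`, `offset`.
#' @return the focal row (single-row data.frame).
#' @export
focal_pixel <- function(cluster) {
  stopifnot(nrow(cluster) >= 1)
  o <- order(-cluster$offset, cluster$lat, cluster$lon)
  cluster[o[1], , drop = FALSE]
}

#' Donor search for one vulnerable area
#'
#' Computes, for the focal pixel's future climate, the genomic vulnerability
#' `ED_j` to the current climate of every cultivation pixel, then chooses a
#' donor per strategy: `optimal` takes the global ED minimum (ties by
#' geographic proximity, then lexicographic coordinates); `near_optimal` /
#' `sub_optimal` take the geographically closest pixel among the 1% / 5%
#' lowest-ED pixels (quantile by rank, `ceiling(n * q)`, at least 1; ED ties
#' ranked by geographic proximity then lexicographic coordinates, so every
#' pool contains the optimal donor). The
#' focal pixel itself is a candidate, so self-donation is possible. The
#' chosen donor's ED is the migration load.
#'
#' @param model a `turnover_model` for this climate model.
#' @param focal single-row data.frame (`pixel_id`, `lat`, `lon`) of the
#'   focal pixel.
#' @param focal_future named vector (or single-row table) of the focal
#'   pixel's future climate metrics.
#' @param candidates `climate_metric_table` of current climate over all
#'   cultivation pixels.
#' @param strategy one of `optimal`, `near_optimal`, `sub_optimal`.
#' @param countries optional named character vector mapping pixel ids to
#'   country labels (for the transboundary flag).
#' @param strategy_q quantiles used by the near/sub-optimal pools.
#' @return single-row data.frame: strategy, focal/donor pixel and
#'   coordinates, `distance_km`, `load`, countries, `transboundary`.
#' @export
donor_search <- function(model, focal, focal_future, candidates,
                         strategy = c("optimal", "near_optimal",
                                      "sub_optimal"),
                         countries = NULL,
                         strategy_q = c(near_optimal = 0.01,
                                        sub_optimal = 0.05)) {
  strategy <- match.arg(strategy)
  n <- nrow(candidates)
  if (n < 2) stop("need >= 2 candidate pixels")
  tf <- gf_transform(model, focal_future)
  if (is.matrix(tf)) tf <- tf[1, ]
  tc <- gf_transform(model, candidates)
  ed <- sqrt(colSums((t(tc) - tf)^2))
  gd <- geodesic_km(focal$lat, focal$lon, candidates$lat, candidates$lon)
  # one deterministic ED ranking (ties: geographically nearest, then
  # lexicographic) shared by all strategies, so every pool contains the
  # optimal donor and the distance/load orderings follow by set inclusion
  rank_ed <- order(ed, gd, candidates$lat, candidates$lon)
  pick <- if (strategy == "optimal") {
    rank_ed[1]
  } else {
    m <- max(1L, ceiling(n * strategy_q[[strategy]]))
    pool <- rank_ed[seq_len(m)]
    pool[order(gd[pool], candidates$lat[pool], candidates$lon[pool])[1]]
  }
  fc <- if (is.null(countries)) NA_character_ else
    unname(countries[focal$pixel_id])
  dc <- if (is.null(countries)) NA_character_ else
    unname(countries[candidates$site_id[pick]])
  data.frame(strategy = strategy,
             focal_pixel = focal$pixel_id,
             focal_lat = focal$lat, focal_lon = focal$lon,
             donor_pixel = candidates$site_id[pick],
             donor_lat = candidates$lat[pick],
             donor_lon = candidates$lon[pick],
             distance_km = unname(gd[pick]), load = unname(ed[pick]),
             focal_country = fc, donor_country = dc,
             transboundary = if (is.null(countries)) NA else
               !identical(fc, dc))
}

#' Assisted-migration plans for every vulnerable area of an ensemble
#'
#' For each climate model: finds vulnerable clusters on that model's offset
#' map, picks each cluster's focal pixel, and runs the donor search for the
#' requested strategies against the model's own turnover fit and pixel
#' climates.
#'
#' @param vmap a `vulnerability_map`.
#' @param fits named list of `turnover_model` per climate model.
#' @param current_metrics,future_metrics named lists of pixel
#'   `climate_metric_table` per climate model.
#' @param countries optional named vector pixel id -> country.
#' @param strategies strategies to evaluate.
#' @param ... passed to [vulnerable_clusters()].
#' @return data.frame of plans (one row per model x cluster x strategy)
#'   with `model` and `cluster` columns; class `migration_plan`.
#' @export
plan_migrations <- function(vmap, fits, current_metrics, future_metrics,
                            countries = NULL,
                            strategies = c("optimal", "near_optimal",
                                           "sub_optimal"), ...) {
  stopifnot(inherits(vmap, "vulnerability_map"))
  plans <- list()
  for (mn in vmap$models) {
    off <- vmap$offsets[vmap$offsets$model == mn, , drop = FALSE]
    cl <- vulnerable_clusters(off, ...)
    if (!nrow(cl)) next
    cand <- current_metrics[[mn]]
    cand <- cand[cand$site_id %in% off$pixel_id, , drop = FALSE]
    fut <- future_metrics[[mn]]
    for (k in sort(unique(cl$cluster))) {
      focal <- focal_pixel(cl[cl$cluster == k, , drop = FALSE])
      ff <- fut[match(focal$pixel_id, fut$site_id), , drop = FALSE]
      if (anyNA(ff$site_id)) stop("future metrics missing focal pixel")
      for (st in strategies) {
        row <- donor_search(fits[[mn]], focal, ff, cand, st, countries)
        row$model <- mn
        row$cluster <- k
        plans[[length(plans) + 1L]] <- row
      }
    }
  }
  out <- if (length(plans)) do.call(rbind, plans) else
    data.frame(strategy = character(0), focal_pixel = character(0),
               focal_lat = numeric(0), focal_lon = numeric(0),
               donor_pixel = character(0), donor_lat = numeric(0),
               donor_lon = numeric(0), distance_km = numeric(0),
               load = numeric(0), focal_country = character(0),
               donor_country = character(0), transboundary = logical(0),
               model = character(0), cluster = integer(0))
  rownames(out) <- NULL
  class(out) <- c("migration_plan", "data.frame")
  out
}

#' Summarise migration plans across the climate-model ensemble
#'
#' Pools the plans of all climate models (each model analysed separately
#' then combined) and reports, per strategy: the number of vulnerable
#' areas, migration distance min/mean/SD/max (km), the percentage of
#' transboundary migrations, and migration load min/mean/max.
#'
#' @param plans a `migration_plan` data.frame.
#' @return data.frame with one row per strategy.
#' @export
summarize_migrations <- function(plans) {
  stopifnot(nrow(plans) >= 1)
  out <- lapply(split(as.data.frame(plans), plans$strategy), function(d) {
    data.frame(strategy = d$strategy[1],
               n_areas = nrow(d),
               dist_min = min(d$distance_km),
               dist_mean = mean(d$distance_km),
               dist_sd = if (nrow(d) > 1) stats::sd(d$distance_km) else 0,
               dist_max = max(d$distance_km),
               transboundary_pct =
                 if (all(is.na(d$transboundary))) NA_real_ else
                   100 * mean(d$transboundary, na.rm = TRUE),
               load_min = min(d$load),
               load_mean = mean(d$load),
               load_max = max(d$load))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$strategy,
                  c("optimal", "near_optimal", "sub_optimal"))), ]
}
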