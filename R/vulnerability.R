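#' Genomic offset between two climates
#'
#' The genomic vulnerability (offset) of a location is the Euclidean
#' distance between its current and future climates after transformation
#' through the fitted turnover functions: the genetic change implied by the
#' climate shift.
#'
#' @param model a `turnover_model`.
#' @param x_current,x_future named vectors (or single-row tables) with all
#'   model predictors.
#' @return non-negative scalar.
#' @export
genomic_offset <- function(model, x_current, x_future) {
  a <- gf_transform(model, x_current)
  b <- gf_transform(model, x_future)
  sqrt(sum((b - a)^2))
}

# convex hull of points, as a polygon matrix (lon, lat), counter-clockwise
hull_polygon <- function(lat, lon) {
  h <- grDevices::chull(lon, lat)
  cbind(lon = lon[h], lat = lat[h])
}

# membership test for a convex polygon, boundary counted as inside
in_convex_hull <- function(lat, lon, poly) {
  nv <- nrow(poly)
  if (nv < 3) return(rep(FALSE, length(lat)))
  inside <- rep(TRUE, length(lat))
  # chull returns clockwise order; check a consistent side for every edge
  sgn <- 0
  for (k in seq_len(nv)) {
    a <- poly[k, ]; b <- poly[if (k == nv) 1L else k + 1L, ]
    cr <- (b[1] - a[1]) * (lat - a[2]) - (b[2] - a[2]) * (lon - a[1])
    if (sgn == 0 && any(cr != 0)) sgn <- sign(cr[which(cr != 0)[1]])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  inside
}

#' Multi-model genomic vulnerability map
#'
#' Computes per-pixel offsets for each climate model (each with its own
#' fitted turnover model and matched current/future metric tables),
#' restricted to pixels whose centers fall inside the convex hull of the
#' landrace coordinates (the cultivation area). Summarises across models
#' with the mean, population SD, coefficient of variation and the stippling
#' flag (mean more than twice the SD, i.e. CV < 0.5: model agreement).
#'
#' @param fits named list of `turnover_model`, one per climate model.
#' @param current_metrics,future_metrics named lists of
#'   `climate_metric_table` over pixels, names matching `fits`.
#' @param landraces landrace table (`lat`, `lon`) delimiting the hull; when
#'   `NULL` all pixels are kept.
#' @param scenario,horizon labels recorded in the result.
#' @return object of class `vulnerability_map`: `offsets` (long
#'   pixel x model table) and `summary` (per-pixel mean/sd/cv/stipple).
#' @export
map_offsets <- function(fits, current_metrics, future_metrics,
                        landraces = NULL, scenario = "rcp85",
                        horizon = "2050") {
  stopifnot(length(fits) >= 1,
            identical(names(fits), names(current_metrics)),
            identical(names(fits), names(future_metrics)))
  models <- names(fits)
  # pixels present in every model's current and future tables
  common <- Reduce(intersect, c(lapply(current_metrics, `[[`, "site_id"),
                                lapply(future_metrics, `[[`, "site_id")))
  all_px <- unique(unlist(lapply(current_metrics, `[[`, "site_id")))
  if (length(common) < length(all_px))
    warning(sprintf("dropping %d pixel(s) missing from some model",
                    length(all_px) - length(common)))
  ref <- current_metrics[[1]]
  ref <- ref[match(common, ref$site_id), c("site_id", "lat", "lon")]
  if (!is.null(landraces)) {
    poly <- hull_polygon(landraces$lat, landraces$lon)
    keep <- in_convex_hull(ref$lat, ref$lon, poly)
    ref <- ref[keep, , drop = FALSE]
  }
  if (!nrow(ref)) stop("no pixels inside the cultivation hull")

  long <- do.call(rbind, lapply(models, function(mn) {
    cur <- current_metrics[[mn]]
    fut <- future_metrics[[mn]]
    tc <- gf_transform(fits[[mn]],
                       cur[match(ref$site_id, cur$site_id), , drop = FALSE])
    tf <- gf_transform(fits[[mn]],
                       fut[match(ref$site_id, fut$site_id), , drop = FALSE])
    data.frame(pixel_id = ref$site_id, lat = ref$lat, lon = ref$lon,
               model = mn, offset = sqrt(rowSums((tf - tc)^2)))
  }))
  rownames(long) <- NULL

  om <- matrix(long$offset, nrow = nrow(ref), ncol = length(models))
  mu <- rowMeans(om)
  sdp <- sqrt(rowMeans((om - mu)^2))  # population SD across the ensemble
  cv <- ifelse(mu > 0, sdp / mu, NA_real_)
  summary <- data.frame(pixel_id = ref$site_id, lat = ref$lat,
                        lon = ref$lon, mean = mu, sd = sdp, cv = cv,
                        stipple = mu > 2 * sdp)
  structure(list(offsets = long, summary = summary, models = models,
                 scenario = scenario, horizon = horizon,
                 sd_convention = "population"),
            class = "vulnerability_map")
}

#' @export
print.vulnerability_map <- function(x, ...) {
  cat(sprintf(
    "vulnerability_map: %d pixels x %d model(s) [%s / %s]; mean offset %.4g\n",
    nrow(x$summary), length(x$models), x$scenario, x$horizon,
    mean(x$summary$mean)))
  invisible(x)
}

#' Per-landrace vulnerability to a common-garden site
#'
#' Offset between the climate at each landrace's origin and the climate of
#' one common-garden site, under a single fitted model. Origin climates
#' outside the model's training range are clamped (with a warning).
#'
#' @param model a `turnover_model`.
#' @param origin_metrics `climate_metric_table` with one row per landrace.
#' @param site_metrics single-row metric table (or named vector) for the
#'   garden site.
#' @return named numeric vector of offsets, one per landrace.
#' @export
landrace_site_vulnerability <- function(model, origin_metrics, site_metrics) {
  X <- as.matrix(origin_metrics[, model$predictors, drop = FALSE])
  out_of_range <- any(sweep(X, 2, model$ranges["lo", ], `<`)) ||
    any(sweep(X, 2, model$ranges["hi", ], `>`))
  if (out_of_range)
    warning("origin climate outside training range; transform clamped")
  to <- gf_transform(model, origin_metrics)
  if (is.data.frame(site_metrics) || is.matrix(site_metrics)) {
    stopifnot(nrow(site_metrics) == 1L)
    ts <- gf_transform(model, site_metrics)[1, ]
  } else ts <- gf_transform(model, site_metrics)
  stats::setNames(sqrt(colSums((t(to) - ts)^2)), origin_metrics$site_id)
}

#' Correlate yield-related traits with genomic vulnerability
#'
#' Product-moment correlation (and two-sided test) of each trait against
#' per-landrace vulnerability; pairs with a missing trait value are dropped
#' and the complete-pair count reported.
#'
#' @param vulns named numeric vector of per-landrace vulnerabilities.
#' @param traits data.frame of trait columns, rows aligned with `vulns`
#'   (or carrying an `id` column matching `names(vulns)`).
#' @return data.frame with trait, r, p, n.
#' @export
correlate_yield <- function(vulns, traits) {
  if ("id" %in% names(traits)) {
    i <- match(names(vulns), traits$id)
    if (anyNA(i)) stop("trait table missing landrace(s)")
    traits <- traits[i, setdiff(names(traits), "id"), drop = FALSE]
  }
  stopifnot(nrow(traits) == length(vulns))
  res <- lapply(names(traits), function(tr) {
    y <- traits[[tr]]
    ok <- !is.na(y) & !is.na(vulns)
    if (sum(ok) < 3) stop("need >= 3 complete pairs for trait ", tr)
    if (stats::sd(y[ok]) == 0)
      stop("zero-variance trait: ", tr, " (correlation undefined)")
    ct <- stats::cor.test(vulns[ok], y[ok], method = "pearson")
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, res)
}
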