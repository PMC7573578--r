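#' Daily climate grid container
#'
#' Holds per-pixel daily series of the five weather variables used by the
#' agro-climate metric catalog: precipitation (mm/day), mean/max/min
#' near-surface air temperature (degrees C) and downwelling shortwave
#' radiation (W/m2). Day indexing is 0-based within a climate year.
#'
#' @param pixels data.frame with columns `pixel_id`, `lat`, `lon` (degrees,
#'   pixel centers).
#' @param precip,tmean,tmax,tmin,srad numeric matrices, one row per pixel and
#'   one column per day; all the same dimension, at least 210 days.
#' @param period,model,scenario character labels (e.g. "current",
#'   "model01", "rcp85").
#' @return An object of class `daily_climate_grid`.
#' @export
daily_climate_grid <- function(pixels, precip, tmean, tmax, tmin, srad,
                               period = "current", model = "obs",
                               scenario = "historical") {
  stopifnot(is.data.frame(pixels),
            all(c("pixel_id", "lat", "lon") %in% names(pixels)))
  if (nrow(pixels) == 0L) stop("degenerate grid: 0 pixels")
  mats <- list(precip = precip, tmean = tmean, tmax = tmax,
               tmin = tmin, srad = srad)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != nrow(pixels)) || length(unique(dims[2, ])) != 1L)
    stop("climate variable matrices must share dimension n_pixels x n_days")
  if (ncol(precip) < 210L)
    stop("daily series must cover at least 210 days (onset + 180-day window)")
  if (any(precip < 0)) stop("negative precipitation in grid")
  if (any(tmin > tmean + 1e-9) || any(tmean > tmax + 1e-9))
    stop("temperature ordering violated: need tmin <= tmean <= tmax")
  if (any(abs(pixels$lat) > 90) || any(abs(pixels$lon) > 180))
    stop("pixel coordinates out of range")
  structure(
    list(pixels = pixels, precip = precip, tmean = tmean, tmax = tmax,
         tmin = tmin, srad = srad, period = period, model = model,
         scenario = scenario),
    class = "daily_climate_grid")
}

#' @export
print.daily_climate_grid <- function(x, ...) {
  cat(sprintf(
    "daily_climate_grid: %d pixels x %d days [%s / %s / %s]\n",
    nrow(x$pixels), ncol(x$precip), x$period, x$model, x$scenario))
  invisible(x)
}

#' Number of days in the grid's climate year
#' @param grid a `daily_climate_grid`
#' @return integer day count
#' @export
n_days <- function(grid) ncol(grid$precip)

#' Restrict a climate grid to a subset of pixels
#'
#' Metrics are per-pixel quantities, so computing them on a subset (e.g.
#' only the pixels containing landraces) gives identical values at much
#' lower cost than the full grid.
#'
#' @param grid a `daily_climate_grid`.
#' @param pixel_ids ids to keep (order preserved, duplicates dropped).
#' @return a `daily_climate_grid` over the requested pixels.
#' @export
subset_pixels <- function(grid, pixel_ids) {
  pixel_ids <- unique(pixel_ids)
  i <- match(pixel_ids, grid$pixels$pixel_id)
  if (anyNA(i))
    stop("unknown pixel id(s): ",
         paste(pixel_ids[is.na(i)], collapse = ", "))
  px <- grid$pixels[i, , drop = FALSE]
  rownames(px) <- NULL
  daily_climate_grid(px, grid$precip[i, , drop = FALSE],
                     grid$tmean[i, , drop = FALSE],
                     grid$tmax[i, , drop = FALSE],
                     grid$tmin[i, , drop = FALSE],
                     grid$srad[i, , drop = FALSE],
                     grid$period, grid$model, grid$scenario)
}
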