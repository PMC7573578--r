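#' Filter SNPs on folded minor allele frequency
#'
#' The folded MAF of a SNP is `min(mean freq, 1 - mean freq)` over
#' landraces; SNPs are kept iff folded MAF is strictly above `threshold`.
#'
#' @param freqs landraces x SNPs numeric matrix of frequencies in \[0, 1\].
#' @param threshold MAF threshold, in (0, 0.5).
#' @return the filtered frequency matrix (possibly 0 columns, with warning).
#' @export
filter_maf <- function(freqs, threshold = 0.10) {
  stopifnot(is.matrix(freqs), threshold > 0, threshold < 0.5)
  if (anyNA(freqs)) stop("missing cells in frequency matrix")
  maf <- folded_maf(freqs)
  keep <- maf > threshold
  if (!any(keep)) warning("no SNP passes the MAF filter")
  freqs[, keep, drop = FALSE]
}

#' Folded minor allele frequency per SNP
#' @param freqs landraces x SNPs matrix.
#' @return named numeric vector, `min(mean, 1 - mean)` per SNP.
#' @export
folded_maf <- function(freqs) {
  mu <- colMeans(freqs)
  pmin(mu, 1 - mu)
}

#' Fit a gradient-forest turnover model
#'
#' Fits one regression random forest per SNP (frequency on all climate
#' predictors; `n_trees` trees, `mtry` predictors per split, bootstrap per
#' tree) and aggregates per-split impurity reductions into one monotone
#' cumulative-importance turnover function per predictor. Out-of-bag R2 is
#' recorded per SNP; negative values are clamped to 0 and such SNPs are
#' excluded from turnover aggregation (only SNPs with predictive power,
#' R2 > 0, contribute). Split importance is binned along each predictor,
#' divided by the empirical density of that predictor's training values
#' (the density of split opportunities), rescaled so the curve's total mass
#' equals the predictor's R2-weighted aggregate importance, and cumulated.
#'
#' Constant predictors are excluded from split sampling (importance 0, flat
#' turnover), so adding one leaves every other turnover function unchanged.
#'
#' @param freqs landraces x SNPs matrix (rownames = landrace/site ids).
#' @param metrics `climate_metric_table` whose `site_id` matches
#'   `rownames(freqs)`.
#' @param n_trees trees per SNP forest.
#' @param seed integer; the fit is deterministic given the seed.
#' @param mtry predictors sampled per split; default `max(1, p/3)` over
#'   varying predictors.
#' @param min_node minimum node size for splitting.
#' @param bins number of turnover bins per predictor.
#' @param predictors optional subset of metric names to use.
#' @return object of class `turnover_model`.
#' @export
gf_fit <- function(freqs, metrics, n_trees = 500L, seed = 1L, mtry = NULL,
                   min_node = 5L, bins = 201L, predictors = NULL) {
  stopifnot(is.matrix(freqs), nrow(freqs) >= 20)
  if (anyNA(freqs)) stop("missing cells in frequency matrix")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies outside [0, 1]")
  cols <- if (is.null(predictors)) metric_columns(metrics) else predictors
  i <- match(rownames(freqs), metrics$site_id)
  if (anyNA(i)) stop("metric table missing site(s): ",
                     paste(rownames(freqs)[is.na(i)], collapse = ", "))
  X <- as.matrix(metrics[i, cols, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  varying <- which(apply(X, 2, function(v) max(v) > min(v)))
  if (!length(varying)) stop("all predictors constant")
  if (is.null(mtry)) mtry <- max(1L, floor(length(varying) / 3))

  snps <- colnames(freqs)
  r2 <- numeric(length(snps))
  names(r2) <- snps
  share <- matrix(0, length(snps), p, dimnames = list(snps, cols))
  rec <- vector("list", length(snps))
  for (s in seq_along(snps)) {
    y <- as.numeric(freqs[, s])
    vy <- sum((y - mean(y))^2)
    fit <- .fit_snp_forest(X, y, varying - 1L, as.integer(n_trees),
                           as.integer(mtry), as.integer(min_node),
                           as.integer(seed + s))
    if (vy > 0) {
      ok <- !is.na(fit$oob_pred)
      mse <- mean((y[ok] - fit$oob_pred[ok])^2)
      r2[s] <- max(0, 1 - mse / (vy / n))
    }
    if (length(fit$split_var)) {
      tot <- sum(fit$split_improvement)
      agg <- vapply(seq_len(p), function(j)
        sum(fit$split_improvement[fit$split_var == j]), numeric(1))
      if (tot > 0) share[s, ] <- agg / tot
    }
    rec[[s]] <- fit[c("split_var", "split_value", "split_improvement")]
  }

  predictive <- which(r2 > 0)
  imp <- if (length(predictive)) {
    colSums(share[predictive, , drop = FALSE] * r2[predictive]) /
      length(predictive)
  } else stats::setNames(numeric(p), cols)

  turnover <- vector("list", p)
  names(turnover) <- cols
  ranges <- rbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  for (j in seq_len(p)) {
    lo <- ranges["lo", j]; hi <- ranges["hi", j]
    edges <- if (hi > lo) seq(lo, hi, length.out = bins + 1L) else c(lo, hi)
    nb <- length(edges) - 1L
    mass <- numeric(nb)
    if (imp[j] > 0 && hi > lo) {
      dens <- stats::density(X[, j], from = lo + (hi - lo) / (2 * nb),
                             to = hi - (hi - lo) / (2 * nb), n = nb)$y
      dens <- pmax(dens, 1e-3 * max(dens))
      for (s in predictive) {
        f <- rec[[s]]
        sel <- f$split_var == j
        if (!any(sel)) next
        tot <- sum(f$split_improvement)
        w <- f$split_improvement[sel] * r2[s] / tot
        b <- pmin(nb, pmax(1L, findInterval(f$split_value[sel], edges,
                                            rightmost.closed = TRUE)))
        mass <- mass + as.numeric(tapply(w, factor(b, levels = seq_len(nb)),
                                         sum, default = 0))
      }
      mass <- mass / dens
      if (sum(mass) > 0) mass <- mass * imp[j] / sum(mass)
    }
    turnover[[j]] <- list(edges = edges, cum = cumsum(mass))
  }

  structure(list(predictors = cols, turnover = turnover, ranges = ranges,
                 r2 = r2, importance = imp, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), min_node = as.integer(min_node),
                 bins = as.integer(bins), seed = as.integer(seed),
                 n_sites = n),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf(
    "turnover_model: %d predictors, %d SNPs (%d with R2 > 0), %d trees/SNP\n",
    length(x$predictors), length(x$r2), sum(x$r2 > 0), x$n_trees))
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("top predictors:\n")
    print(utils::head(round(top, 5), 5))
  }
  invisible(x)
}

# evaluate one predictor's cumulative-importance step function; jumps occur
# at bin right edges so F(training min) = 0, F(>= max) = total importance
eval_turnover <- function(tv, x) {
  edges <- tv$edges
  x <- pmin(edges[length(edges)], pmax(edges[1], x))
  idx <- findInterval(x, edges[-1], rightmost.closed = FALSE)
  c(0, tv$cum)[idx + 1L]
}

#' Transform climate vectors through the fitted turnover functions
#'
#' Maps climate metric values into genomic-composition space: component `p`
#' is the cumulative importance `F_p(x_p)` with `x_p` clamped to the
#' training range. Componentwise monotone in the input.
#'
#' @param model a `turnover_model`.
#' @param x named numeric vector, or data.frame/matrix with one column per
#'   model predictor (extra columns ignored).
#' @return numeric vector (or matrix, rows matching `x`) of transformed
#'   components, one per predictor.
#' @export
gf_transform <- function(model, x) {
  stopifnot(inherits(model, "turnover_model"))
  if (is.null(dim(x))) {
    if (!all(model$predictors %in% names(x)))
      stop("missing predictor(s): ",
           paste(setdiff(model$predictors, names(x)), collapse = ", "))
    vapply(model$predictors,
           function(p) eval_turnover(model$turnover[[p]], x[[p]]),
           numeric(1))
  } else {
    xd <- as.data.frame(x)
    if (!all(model$predictors %in% names(xd)))
      stop("missing predictor(s): ",
           paste(setdiff(model$predictors, names(xd)), collapse = ", "))
    out <- vapply(model$predictors,
                  function(p) eval_turnover(model$turnover[[p]], xd[[p]]),
                  numeric(nrow(xd)))
    if (nrow(xd) == 1L) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, model$predictors))
    out
  }
}

#' Fraction of SNPs predictable from climate
#'
#' @param model a `turnover_model`.
#' @return list: `fraction` = share of SNPs with out-of-bag R2 > 0,
#'   `n_predictive`, `n_total`.
#' @export
fraction_predicted <- function(model) {
  stopifnot(inherits(model, "turnover_model"))
  np <- sum(model$r2 > 0)
  list(fraction = np / length(model$r2), n_predictive = np,
       n_total = length(model$r2))
}

#' Save / load a turnover model as a JSON bundle
#'
#' Serializes predictor names, bin edges, cumulative values, per-SNP R2 and
#' hyperparameters to a single JSON file at full double precision.
#'
#' @param model a `turnover_model`.
#' @param path file path.
#' @return `gf_save` the path invisibly; `gf_load` the restored model.
#' @export
gf_save <- function(model, path) {
  stopifnot(inherits(model, "turnover_model"))
  obj <- unclass(model)
  obj$ranges <- list(lo = unname(obj$ranges["lo", ]),
                     hi = unname(obj$ranges["hi", ]))
  obj$r2 <- as.list(obj$r2)            # keep SNP names in JSON
  obj$importance <- as.list(obj$importance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gf_save
#' @export
gf_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$ranges <- rbind(lo = obj$ranges$lo, hi = obj$ranges$hi)
  colnames(obj$ranges) <- obj$predictors
  obj$turnover <- lapply(obj$turnover, function(tv)
    list(edges = as.numeric(tv$edges), cum = as.numeric(tv$cum)))
  names(obj$turnover) <- obj$predictors
  obj$importance <- unlist(obj$importance)[obj$predictors]
  obj$r2 <- unlist(obj$r2)
  structure(obj, class = "turnover_model")
}
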