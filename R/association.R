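#' PCA of allele frequencies
#'
#' Centered (not scaled) principal component analysis of the landrace x SNP
#' frequency matrix, summarising population structure.
#'
#' @param freqs landraces x SNPs matrix.
#' @return list: `scores` (landraces x components), `var_explained`
#'   (fractions summing to 1), `sdev`.
#' @export
pca_freqs <- function(freqs) {
  stopifnot(nrow(freqs) >= 3)
  pc <- stats::prcomp(freqs, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev)
}

#' Choose the number of latent factors from the PCA screeplot
#'
#' Applies the largest-drop rule to the eigenvalue screeplot: K is the index
#' maximising the difference between successive eigenvalues, capped at
#' `k_max`. A low-structure warning is raised when the top eigenvalue is
#' less than 1.5x the median eigenvalue. Pass `override` to impose a K
#' chosen by other diagnostics.
#'
#' @param freqs landraces x SNPs matrix.
#' @param k_max upper cap on K.
#' @param override integer; when given, returned as-is.
#' @return integer K.
#' @export
choose_k <- function(freqs, k_max = 10L, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(nrow(freqs) >= 3)
  ev <- pca_freqs(freqs)$sdev^2
  if (ev[1] < 1.5 * stats::median(ev))
    warning("low structure: top eigenvalue < 1.5x median eigenvalue")
  drops <- -diff(ev)
  k <- which.max(drops[seq_len(min(length(drops), k_max))])
  as.integer(min(k, k_max))
}

#' Latent-factor association of SNP frequencies with a phenotype
#'
#' Tests each SNP's allele frequency against the phenotype while
#' conditioning on K latent factors that capture unobserved confounding
#' (population structure). Factors are the first K principal-component
#' scores of the centered frequency matrix (ridge-style low-rank
#' estimate); each SNP is then regressed on phenotype plus factors, giving
#' an effect size, a z-score, and a two-sided p-value. z-scores are
#' recalibrated by the genomic-inflation factor (median observed chi-square
#' over its theoretical median) before computing the calibrated p-values
#' used for FDR selection. With `K = 0` the statistics reduce exactly to
#' simple linear regression.
#'
#' @param freqs landraces x SNPs matrix (typically MAF-filtered at 5%).
#' @param phenotype numeric vector aligned with rows of `freqs` (complete).
#' @param K number of latent factors (< n_landraces - 2).
#' @return object of class `association_result`: data.frame `stats` (snp,
#'   effect, z, p_raw, p), `K`, `gif`.
#' @export
lfmm_fit <- function(freqs, phenotype, K = 5L) {
  n <- nrow(freqs)
  stopifnot(length(phenotype) == n)
  if (anyNA(phenotype)) stop("phenotype must be complete")
  K <- as.integer(K)
  if (K >= n - 2L) stop("K must be smaller than n_landraces - 2")
  U <- if (K > 0) pca_freqs(freqs)$scores[, seq_len(K), drop = FALSE]
       else NULL
  D <- cbind(1, phenotype, U)
  qrD <- qr(D)
  coef <- qr.coef(qrD, freqs)
  fitted <- D %*% coef
  res <- freqs - fitted
  df <- n - ncol(D)
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrD))[2, 2]
  se <- sqrt(sigma2 * xtxinv)
  eff <- coef[2, ]
  tt <- ifelse(se > 0, eff / se, 0)
  p_t <- 2 * stats::pt(-abs(tt), df)
  z <- sign(tt) * stats::qnorm(pmax(p_t / 2, 1e-300), lower.tail = FALSE)
  gif <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
  if (!is.finite(gif) || gif <= 0) gif <- 1
  zcal <- z / sqrt(gif)
  p <- 2 * stats::pnorm(-abs(zcal))
  stats_df <- data.frame(snp = colnames(freqs), effect = unname(eff),
                         z = unname(z), z_cal = unname(zcal),
                         p_raw = unname(p_t), p = unname(p))
  structure(list(stats = stats_df, K = K, gif = gif, df = df),
            class = "association_result")
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up BH adjustment of p-values and selection at level `alpha`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return list: `q` (BH-adjusted q-values, input order), `selected`
#'   (logical), `n_selected`.
#' @export
fdr_select <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  sel <- q <= alpha
  list(q = q, selected = sel, n_selected = sum(sel))
}

#' Q-Q calibration table of association p-values
#'
#' Expected vs observed -log10 p-values, for inspecting test calibration.
#'
#' @param p numeric p-values.
#' @return data.frame with `expected` and `observed` (-log10, sorted).
#' @export
qq_table <- function(p) {
  m <- length(p)
  data.frame(expected = -log10(stats::ppoints(m)),
             observed = -log10(sort(p)))
}

#' Compare climate predictability of selected vs all SNPs
#'
#' Two-sided Wilcoxon rank-sum test of the per-SNP turnover-model R2 of a
#' selected SNP set (e.g. flowering-time associated SNPs) against the R2 of
#' all SNPs, with both means reported.
#'
#' @param model a `turnover_model` fitted on observed-climate metrics.
#' @param selected character ids of the selected SNPs (subset of the
#'   model's SNPs).
#' @return list: `mean_selected`, `mean_all`, `p` (Wilcoxon), `n_selected`,
#'   `n_all`.
#' @export
compare_r2 <- function(model, selected) {
  stopifnot(inherits(model, "turnover_model"))
  if (!length(selected)) stop("empty selected SNP set")
  missing <- setdiff(selected, names(model$r2))
  if (length(missing))
    stop("selected SNP(s) absent from model: ",
         paste(utils::head(missing, 5), collapse = ", "))
  r2_sel <- model$r2[selected]
  r2_all <- model$r2
  p <- if (length(unique(c(r2_sel, r2_all))) == 1) 1 else
    suppressWarnings(stats::wilcox.test(r2_sel, r2_all)$p.value)
  list(mean_selected = mean(r2_sel), mean_all = mean(r2_all), p = p,
       n_selected = length(r2_sel), n_all = length(r2_all))
}
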