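# Cell-level quality control and normalization.

#' QC thresholds
#'
#' Closed-interval filters on features detected, total counts, and percent
#' mitochondrial counts, plus the residual-filter SD multiplier.
#'
#' @param n_feature_range Detected-feature interval (default `c(500, 3000)`).
#' @param n_count_range Total-count interval (default `c(1000, 30000)`).
#' @param pct_mito_range Percent-mitochondrial interval (default `c(0, 30)`).
#' @param residual_sd_k SD multiplier for [residual_filter()] (default 3).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(n_feature_range = c(500, 3000),
                          n_count_range = c(1000, 30000),
                          pct_mito_range = c(0, 30),
                          residual_sd_k = 3) {
  for (r in list(n_feature_range, n_count_range, pct_mito_range))
    if (length(r) != 2L || r[1] > r[2]) stop("threshold ranges must be [lo, hi] with lo <= hi")
  if (residual_sd_k <= 0) stop("residual_sd_k must be positive")
  structure(list(n_feature_range = n_feature_range,
                 n_count_range = n_count_range,
                 pct_mito_range = pct_mito_range,
                 residual_sd_k = residual_sd_k),
            class = "qc_thresholds")
}

#' Threshold QC filter
#'
#' Keeps exactly the cells whose detected features, total counts, and percent
#' mitochondrial counts fall inside the closed threshold ranges.
#' `pct_mito = 100 * mito counts / total counts`, defined as 0 for cells with
#' zero total counts (such cells fail the count range anyway under defaults).
#'
#' @param counts Raw counts, cells x genes (non-negative).
#' @param mito_mask Logical vector over genes marking mitochondrial genes;
#'   if `NULL`, genes whose name starts with `mito_prefix` are used.
#' @param thresholds A [qc_thresholds()] object.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return List: `matrix` (filtered counts), `report` (per-cell metrics and
#'   pass flags; a cell passes overall iff it passes every criterion),
#'   `n_before`, `n_after`.
#' @export
threshold_filter <- function(counts, mito_mask = NULL,
                             thresholds = qc_thresholds(),
                             mito_prefix = "mt-") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(mito_mask)) {
    mito_mask <- if (!is.null(colnames(counts)))
      startsWith(tolower(colnames(counts)), tolower(mito_prefix))
    else rep(FALSE, ncol(counts))
  }
  stopifnot(length(mito_mask) == ncol(counts))
  n_count <- rowSums(counts)
  n_feature <- rowSums(counts > 0)
  mito <- if (any(mito_mask)) rowSums(counts[, mito_mask, drop = FALSE]) else 0
  pct_mito <- ifelse(n_count > 0, 100 * mito / n_count, 0)
  th <- thresholds
  pass_feature <- n_feature >= th$n_feature_range[1] & n_feature <= th$n_feature_range[2]
  pass_count <- n_count >= th$n_count_range[1] & n_count <= th$n_count_range[2]
  pass_mito <- pct_mito >= th$pct_mito_range[1] & pct_mito <= th$pct_mito_range[2]
  pass <- pass_feature & pass_count & pass_mito
  if (!any(pass)) warning("threshold_filter removed every cell")
  report <- data.frame(barcode = rownames(counts) %||% seq_len(nrow(counts)),
                       n_count = n_count, n_feature = n_feature,
                       pct_mito = pct_mito,
                       pass_feature = pass_feature, pass_count = pass_count,
                       pass_mito = pass_mito, pass = pass,
                       row.names = NULL)
  list(matrix = counts[pass, , drop = FALSE], report = report,
       n_before = nrow(counts), n_after = sum(pass))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residual-based count/feature concordance filter
#'
#' Fits an ordinary least-squares line `n_feature ~ n_count` and keeps cells
#' whose residual lies within `k` standard deviations of the mean residual
#' (zero by construction for OLS). Cells where total counts do not predict
#' detected features are thereby excluded.
#'
#' @param n_count,n_feature Per-cell totals and feature counts.
#' @param k SD multiplier (default 3); `Inf` keeps everything.
#' @return Logical keep mask.
#' @export
residual_filter <- function(n_count, n_feature, k = 3) {
  stopifnot(length(n_count) == length(n_feature))
  n <- length(n_count)
  if (n < 3L) {
    warning("fewer than 3 cells; residual filter keeps all")
    return(rep(TRUE, n))
  }
  fit <- stats::lm.fit(cbind(1, n_count), n_feature)
  res <- fit$residuals
  s <- stats::sd(res)  # n - 1 denominator
  # exactly collinear input leaves only floating-point jitter in the
  # residuals; treat such SDs as zero and keep everything
  tol <- sqrt(.Machine$double.eps) * max(1, stats::sd(n_feature))
  if (!is.finite(s) || s <= tol) return(rep(TRUE, n))
  abs(res - mean(res)) <= k * s
}

#' Log-normalize counts
#'
#' Per-cell library-size normalization on the natural-log scale:
#' `log(1 + scale_factor * count / cell_total)`. Cells with zero total counts
#' map to all-zero rows.
#'
#' @param counts Cells x genes non-negative counts.
#' @param scale_factor Scale factor (default 1e4).
#' @return Normalized matrix, same dimensions.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- rowSums(counts)
  denom <- ifelse(tot > 0, tot, 1)
  log1p(scale_factor * counts / denom)
}
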