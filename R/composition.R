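# Bootstrap estimation of subpopulation composition per cohort.

#' Bootstrap subtype proportions with percentile confidence intervals
#'
#' Per cohort, the point estimate is the observed subtype fraction over all
#' cells; each bootstrap iteration draws `n_sample` cells with replacement
#' (also when the cohort holds fewer cells) and records subtype fractions,
#' and the confidence interval is the percentile interval of the bootstrap
#' fractions (linear interpolation between order statistics).
#'
#' @param subtype Per-cell subtype labels.
#' @param cohort Per-cell cohort labels (a single cohort if omitted).
#' @param n_sample Cells drawn per iteration (default 1000).
#' @param n_boot Bootstrap iterations (default 100).
#' @param ci Confidence level (default 0.95).
#' @param seed Integer seed; estimates are deterministic given the seed.
#' @return data.frame of class `composition_estimate`: `cohort`, `subtype`,
#'   `proportion`, `ci_low`, `ci_high`, `n_cells`, `n_boot`, `n_sample`.
#'   Within a cohort the proportions sum to 1; subtypes absent from a cohort
#'   get proportion 0 with CI `[0, 0]`.
#' @export
bootstrap_proportions <- function(subtype, cohort = NULL, n_sample = 1000,
                                  n_boot = 100, ci = 0.95, seed = 1) {
  if (is.null(cohort)) cohort <- rep("all", length(subtype))
  stopifnot(length(subtype) == length(cohort), n_boot >= 1, n_sample >= 1)
  set.seed(as.integer(seed))
  subs <- sort(unique(subtype))
  alpha2 <- (1 - ci) / 2
  out <- list()
  for (co in sort(unique(cohort))) {
    lab <- subtype[cohort == co]
    if (!length(lab)) next
    point <- vapply(subs, function(s) mean(lab == s), numeric(1))
    boot <- matrix(0, n_boot, length(subs), dimnames = list(NULL, subs))
    for (b in seq_len(n_boot)) {
      draw <- lab[sample.int(length(lab), n_sample, replace = TRUE)]
      boot[b, ] <- vapply(subs, function(s) mean(draw == s), numeric(1))
    }
    qs <- apply(boot, 2L, stats::quantile, probs = c(alpha2, 1 - alpha2),
                names = FALSE)
    out[[co]] <- data.frame(cohort = co, subtype = subs,
                            proportion = point,
                            ci_low = qs[1L, ], ci_high = qs[2L, ],
                            n_cells = length(lab), n_boot = n_boot,
                            n_sample = n_sample, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("composition_estimate", class(res))
  res
}

#' Compare compositions across cohorts by CI overlap
#'
#' For every subtype and cohort pair, the difference is called significant
#' iff the confidence intervals are strictly disjoint (one interval's lower
#' bound exceeds the other's upper bound; touching endpoints are not
#' significant). Subtypes missing from a cohort are treated as `[0, 0]`.
#'
#' @param estimates A `composition_estimate` (rbind of cohorts is fine).
#' @return data.frame: `subtype`, `cohort_a`, `cohort_b`, per-cohort
#'   intervals, `significant`.
#' @export
compare_compositions <- function(estimates) {
  est <- as.data.frame(estimates)
  cohorts <- sort(unique(est$cohort))
  if (length(cohorts) < 2L) stop("need at least 2 cohorts")
  subs <- sort(unique(est$subtype))
  get <- function(co, s) {
    r <- est[est$cohort == co & est$subtype == s, ]
    if (!nrow(r)) c(0, 0) else c(r$ci_low[1L], r$ci_high[1L])
  }
  rows <- list()
  for (s in subs) for (i in seq_along(cohorts)) for (j in seq_along(cohorts)) {
    if (j <= i) next
    a <- get(cohorts[i], s); b <- get(cohorts[j], s)
    rows[[length(rows) + 1L]] <- data.frame(
      subtype = s, cohort_a = cohorts[i], cohort_b = cohorts[j],
      ci_low_a = a[1], ci_high_a = a[2], ci_low_b = b[1], ci_high_b = b[2],
      significant = a[1] > b[2] || b[1] > a[2])
  }
  do.call(rbind, rows)
}
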