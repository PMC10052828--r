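# Beta-hurdle attribution of gene expression to cell types.
#
# Per gene x cell type x cohort, expression on the unit interval is modeled
# as a point mass at zero plus a Beta(alpha, beta) component. Shapes are
# chosen by minimum-distance (maximum goodness-of-fit) estimation against
# the empirical CDF of nonzero values; the dropout probability is then
# iterated over a grid, attributing part of the observed zeros to technical
# non-detection. Expected values E[Y] = alpha/(alpha+beta) = 1/(1 + beta/alpha),
# scaled by cell counts, yield each cell type's share Q of a gene's total
# expression; genes whose target-type share clears a threshold in every
# cohort are called cell-type specific.

#' Rescale non-negative expression onto the open unit interval
#'
#' Divides by `max(v) * (1 + eps)` so the largest value maps strictly below 1
#' and zeros stay zero; the mapping is monotone and invariant to positive
#' scaling of the input.
#'
#' @param values Non-negative per-cell expression for one gene.
#' @param eps Headroom keeping the support open (default 1e-6).
#' @return List `values` (rescaled), `scale` (the divisor); `NULL` when the
#'   input is all zero (no-fit signal).
#' @export
rescale_to_unit <- function(values, eps = 1e-6) {
  if (any(values < 0)) stop("expression values must be non-negative")
  m <- max(values)
  if (m <= 0) return(NULL)
  s <- m * (1 + eps)
  list(values = values / s, scale = s)
}

# Two-sided KS distance between sorted sample xs and a CDF vector p = F(xs).
.ks_dist <- function(p, n = length(p)) {
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Fit beta shapes by minimum Kolmogorov-Smirnov distance
#'
#' Searches a coarse log-spaced grid over `[range[1], range[2]]^2` (always
#' including the uniform candidate `(1, 1)`), then refines from the best grid
#' point by Nelder-Mead on log-shapes. The objective is the two-sided
#' sup-distance between the empirical CDF (right-continuous) and the
#' Beta(alpha, beta) CDF; the returned distance never exceeds that of any
#' evaluated candidate.
#'
#' @param x Nonzero values on (0, 1).
#' @param grid_n Grid points per axis (default 10).
#' @param range Shape search range (default `c(0.01, 100)`).
#' @param n_min Minimum number of values required (default 20).
#' @return List `alpha`, `beta_`, `ks_distance`; `NULL` with a warning when
#'   fewer than `n_min` values are supplied (low-support signal).
#' @export
fit_beta_ks <- function(x, grid_n = 10, range = c(0.01, 100), n_min = 20) {
  if (length(x) < n_min) {
    warning("fewer than ", n_min, " nonzero values; beta fit skipped")
    return(NULL)
  }
  if (any(x <= 0) || any(x >= 1)) stop("values must lie strictly in (0, 1)")
  xs <- sort(x)
  n <- length(xs)
  obj <- function(par) .ks_dist(stats::pbeta(xs, exp(par[1]), exp(par[2])), n)
  ax <- log(exp(seq(log(range[1]), log(range[2]), length.out = grid_n)))
  cand <- as.matrix(expand.grid(a = ax, b = ax))
  cand <- rbind(cand, c(0, 0))  # uniform Beta(1, 1)
  vals <- apply(cand, 1L, obj)
  best <- which.min(vals)
  opt <- stats::optim(cand[best, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 500))
  if (opt$value <= vals[best]) {
    par <- opt$par; ks <- opt$value
  } else {
    par <- cand[best, ]; ks <- vals[best]
  }
  list(alpha = unname(exp(par[1])), beta_ = unname(exp(par[2])),
       ks_distance = ks)
}

#' Fit the beta-hurdle model with iterated dropout probability
#'
#' Beta shapes are fit to the nonzero values by [fit_beta_ks()]. The dropout
#' probability `d` is then iterated over a grid on `[0, 1]`: a fraction `d`
#' of the observed zeros is attributed to technical dropout (non-detections
#' carrying no information about the expression law) and excluded, while the
#' remaining zeros stay as true zeros with model point mass
#' `pi0 = zero_fraction * (1 - d)`. The KS distance between the retained
#' sample and the hurdle model is minimized over `d`; ties break toward
#' larger `d` (more dropout), so fully beta-distributed data with uniformly
#' missing cells select `d = 1`.
#'
#' @param values Per-cell expression on `[0, 1)`, zeros included.
#' @param dropout_grid_step Grid step for `d` (default 0.01).
#' @param n_min Minimum nonzero values required (default 20).
#' @param ... Passed to [fit_beta_ks()].
#' @return Object of class `beta_hurdle_fit`: `alpha`, `beta_`, `pr_dropout`,
#'   `pi0`, `zero_fraction`, `ks_distance`, `n_cells`, `n_nonzero`;
#'   `NULL` when all values are zero or nonzero support is below `n_min`.
#' @export
fit_hurdle <- function(values, dropout_grid_step = 0.01, n_min = 20, ...) {
  if (any(values < 0) || any(values >= 1)) stop("values must lie in [0, 1)")
  n <- length(values)
  nz <- values[values > 0]
  n0 <- n - length(nz)
  if (!length(nz)) {
    warning("all values are zero; no fit")
    return(NULL)
  }
  bfit <- fit_beta_ks(nz, n_min = n_min, ...)
  if (is.null(bfit)) return(NULL)
  xs <- sort(nz)
  grid <- seq(0, 1, by = dropout_grid_step)
  pbx <- stats::pbeta(xs, bfit$alpha, bfit$beta_)
  ks <- vapply(grid, function(d) {
    m0 <- round(n0 * (1 - d))     # zeros retained as true non-expressors
    # retained sample (true zeros + nonzero values) vs the expression law of
    # detected expressing cells: retained zeros are misfit mass, so the KS
    # improves as more observed zeros are attributed to dropout
    .ks_dist(c(rep(0, m0), pbx), m0 + length(xs))
  }, numeric(1))
  best <- max(which(ks <= min(ks) + 1e-12))  # ties toward larger d
  d <- grid[best]
  structure(list(alpha = bfit$alpha, beta_ = bfit$beta_,
                 pr_dropout = d, pi0 = n0 / n * (1 - d),
                 zero_fraction = n0 / n, ks_distance = ks[best],
                 ks_nonzero = bfit$ks_distance,
                 n_cells = n, n_nonzero = length(nz)),
            class = "beta_hurdle_fit")
}

#' Hurdle model CDF
#'
#' Mixture CDF with point mass `pi0 = zero_fraction * (1 - pr_dropout)` at
#' zero and weight `1 - pi0` on the fitted beta: `F(0) = pi0` exactly.
#'
#' @param fit A `beta_hurdle_fit`.
#' @param q Quantiles in `[0, 1]`.
#' @return `F(q)`.
#' @export
hurdle_cdf <- function(fit, q) {
  stopifnot(inherits(fit, "beta_hurdle_fit"))
  ifelse(q < 0, 0, fit$pi0 + (1 - fit$pi0) * stats::pbeta(q, fit$alpha, fit$beta_))
}

#' Expected expression under a beta-hurdle fit
#'
#' Mode `"beta_mean"` (default) is the plain beta mean written as
#' `1/(1 + beta/alpha)` (equal to `alpha/(alpha+beta)`); mode `"mixture"`
#' scales it by the non-zero mass `1 - pi0`, which coincides with the default
#' when all zeros are attributed to dropout (`pr_dropout = 1`).
#'
#' @param fit A `beta_hurdle_fit` (or any list with `alpha`, `beta_`, `pi0`).
#' @param mode `"beta_mean"` or `"mixture"`.
#' @return Expected value in `[0, 1]`.
#' @export
expected_value <- function(fit, mode = c("beta_mean", "mixture")) {
  mode <- match.arg(mode)
  e <- 1 / (1 + fit$beta_ / fit$alpha)
  if (mode == "mixture") e <- (1 - fit$pi0) * e
  e
}

#' Fit beta-hurdle models per gene x cell type x cohort
#'
#' Pools each cohort's cells of each type, rescales each gene's values to the
#' open unit interval ([rescale_to_unit()]), and fits [fit_hurdle()]. Genes
#' with no nonzero cell, or fewer than `n_min` nonzero cells, in a (type,
#' cohort) stratum are skipped there (they contribute zero expected value).
#'
#' @param expr Cells x genes log-normalized expression (non-negative).
#' @param cell_meta data.frame with `cell_type` and `cohort` aligned to rows
#'   of `expr`.
#' @param mode Expected-value mode, see [expected_value()].
#' @param dropout_grid_step,n_min Passed to [fit_hurdle()].
#' @param verbose Emit progress messages.
#' @return List of class `hurdle_fits`: `fits` (data.frame, one row per
#'   fitted stratum), `expected` (per cohort: gene x cell type matrix of
#'   expected values, 0 where skipped), `cell_counts` (per cohort: named
#'   vector).
#' @export
fit_cell_type_models <- function(expr, cell_meta, mode = "beta_mean",
                                 dropout_grid_step = 0.01, n_min = 20,
                                 verbose = FALSE) {
  stopifnot(nrow(expr) == nrow(cell_meta))
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  colnames(expr) <- genes
  cohorts <- sort(unique(cell_meta$cohort))
  types <- sort(unique(cell_meta$cell_type))
  expected <- list(); counts <- list(); rows <- list()
  for (co in cohorts) {
    emat <- matrix(0, length(genes), length(types),
                   dimnames = list(genes, types))
    nct <- stats::setNames(integer(length(types)), types)
    co_cells <- which(cell_meta$cohort == co)
    # shared per-gene scale across the cohort's cells, so expected values
    # stay comparable across cell types within the cohort
    gmax <- apply(expr[co_cells, , drop = FALSE], 2L, max)
    scale <- gmax * (1 + 1e-6)
    for (ty in types) {
      idx <- which(cell_meta$cohort == co & cell_meta$cell_type == ty)
      nct[ty] <- length(idx)
      if (!length(idx)) next
      if (verbose) message("fitting ", co, " / ", ty, " (", length(idx), " cells)")
      sub <- expr[idx, , drop = FALSE]
      for (g in genes) {
        if (gmax[g] <= 0 || max(sub[, g]) <= 0) next
        fit <- suppressWarnings(
          fit_hurdle(sub[, g] / scale[g], dropout_grid_step = dropout_grid_step,
                     n_min = n_min))
        if (is.null(fit)) next
        emat[g, ty] <- expected_value(fit, mode = mode)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, cell_type = ty, cohort = co,
          alpha = fit$alpha, beta_ = fit$beta_,
          pr_dropout = fit$pr_dropout, zero_fraction = fit$zero_fraction,
          ks_distance = fit$ks_distance, n_cells = fit$n_cells,
          n_nonzero = fit$n_nonzero,
          expected = emat[g, ty])
      }
    }
    expected[[co]] <- emat
    counts[[co]] <- nct
  }
  structure(list(fits = if (length(rows)) do.call(rbind, rows) else NULL,
                 expected = expected, cell_counts = counts),
            class = "hurdle_fits")
}

#' Cell-type contribution table
#'
#' Given per-gene expected values per cell type and the cohort's cell counts,
#' computes the contribution terms `E[Y_ct] * N_ct` and each type's relative
#' share `Q = term / sum(terms)`. Rows whose terms are all zero are flagged
#' undefined (Q = NA).
#'
#' @param expected Gene x cell type matrix of expected values.
#' @param cell_counts Named non-negative vector, cells per type.
#' @return List of class `contribution_table`: `q` (gene x type shares),
#'   `terms`, `undefined` (logical per gene).
#' @export
contribution_table <- function(expected, cell_counts) {
  expected <- as.matrix(expected)
  if (any(cell_counts < 0)) stop("cell counts must be non-negative")
  miss <- setdiff(colnames(expected), names(cell_counts))
  if (length(miss)) stop("no cell count for type(s): ", paste(miss, collapse = ", "))
  terms <- sweep(expected, 2L, cell_counts[colnames(expected)], `*`)
  tot <- rowSums(terms)
  undefined <- tot <= 0
  q <- terms / ifelse(tot > 0, tot, NA_real_)
  structure(list(q = q, terms = terms, undefined = undefined),
            class = "contribution_table")
}

#' Call cell-type-specific genes across cohorts
#'
#' A gene is called specific to `target` iff its relative contribution Q for
#' the target type is at least `tau` in every cohort (genes undefined in any
#' cohort are not called). Output is sorted by the minimum-over-cohorts Q,
#' descending.
#'
#' @param tables Named list of [contribution_table()] objects, one per cohort.
#' @param target Target cell type (e.g. `"beta"`).
#' @param tau Calling threshold (default 0.8).
#' @return data.frame: `gene_id`, per-cohort `Q_<cohort>` columns, `min_q`,
#'   `called`.
#' @export
call_specific_genes <- function(tables, target, tau = 0.8) {
  stopifnot(length(tables) >= 1)
  for (tb in tables) {
    if (!inherits(tb, "contribution_table")) stop("tables must be contribution_table objects")
    if (!target %in% colnames(tb$q))
      stop("target cell type '", target, "' absent from a cohort's table")
  }
  sets <- lapply(tables, function(tb) rownames(tb$q))
  genes <- Reduce(intersect, sets)
  if (!length(genes)) stop("no genes shared across cohorts")
  if (any(vapply(sets, length, 1L) != length(genes)))
    message("gene universes differ across cohorts; using the intersection (",
            length(genes), " genes)")
  qm <- vapply(tables, function(tb) tb$q[genes, target], numeric(length(genes)))
  qm <- matrix(qm, nrow = length(genes),
               dimnames = list(genes, names(tables)))
  min_q <- apply(qm, 1L, function(v) if (anyNA(v)) NA_real_ else min(v))
  called <- !is.na(min_q) & min_q >= tau
  out <- data.frame(gene_id = genes, qm, min_q = min_q, called = called,
                    check.names = FALSE, row.names = NULL)
  colnames(out)[seq_along(tables) + 1L] <- paste0("Q_", names(tables))
  out[order(-ifelse(is.na(out$min_q), -Inf, out$min_q)), , drop = FALSE]
}

#' Cullen-Frey distribution diagnostic
#'
#' Locates a sample in the (squared skewness, kurtosis) plane together with a
#' bootstrap cloud, the standard diagnostic for identifying a candidate
#' distribution family (the beta family occupies the band between the
#' impossible boundary `kurtosis = skewness^2 + 1` and the gamma line
#' `kurtosis = 3 + 1.5 * skewness^2`). Moments are Pearson sample moments
#' (uncorrected).
#'
#' @param x Numeric sample (>= 10 values).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Optional seed for the bootstrap.
#' @return List: `skewness_sq`, `kurtosis`, `boot` (data.frame of resampled
#'   statistics), `beta_region` (function of skewness^2 returning the
#'   `c(lower, upper)` kurtosis bounds).
#' @export
cullen_frey_diagnostic <- function(x, n_boot = 200, seed = NULL) {
  if (length(x) < 10) stop("need at least 10 values")
  if (stats::sd(x) == 0) stop("constant input: moments undefined")
  if (!is.null(seed)) set.seed(as.integer(seed))
  stat <- function(v) {
    m <- mean(v); s2 <- mean((v - m)^2)
    c(skew = mean((v - m)^3) / s2^1.5, kurt = mean((v - m)^4) / s2^2)
  }
  pt <- stat(x)
  boot <- t(vapply(seq_len(n_boot),
                   function(i) stat(sample(x, replace = TRUE)),
                   numeric(2)))
  list(skewness_sq = unname(pt["skew"]^2), kurtosis = unname(pt["kurt"]),
       boot = data.frame(skewness_sq = boot[, "skew"]^2,
                         kurtosis = boot[, "kurt"]),
       beta_region = function(ss) c(lower = ss + 1, upper = 3 + 1.5 * ss))
}
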