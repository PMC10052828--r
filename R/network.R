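# Weighted co-expression network analysis on bulk samples.
#
# Pipeline: TMM normalization -> rank-based inverse normal transform ->
# biweight midcorrelation -> unsigned soft-thresholded adjacency -> TOM ->
# average-linkage modules -> eigengenes -> module-trait correlation ->
# intramodular connectivity and differential connectivity between cohorts.

#' TMM-normalize bulk counts
#'
#' Trimmed-mean-of-M-values scaling factors (edgeR) and log2
#' counts-per-million on the effective library sizes, with a 0.5 prior
#' count. Two depth-scaled copies of the same sample get identical factors
#' (TMM corrects composition, not depth); samples carrying extra
#' high-expression content receive a factor below 1 so their effective
#' library size absorbs it.
#'
#' @param counts Samples x genes non-negative counts.
#' @param log Return log2 values (default TRUE).
#' @return Samples x genes normalized matrix with attribute `norm_factors`.
#' @export
normalize_bulk <- function(counts, log = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0)) stop("sample with zero total counts")
  dge <- edgeR::DGEList(counts = t(counts))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  out <- t(edgeR::cpm(dge, log = log, prior.count = 0.5))
  attr(out, "norm_factors") <- stats::setNames(dge$samples$norm.factors,
                                               rownames(counts))
  out
}

#' Rank-based inverse normal transform
#'
#' Per gene, maps values to standard-normal scores via the Blom offset,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties sharing the average rank.
#' Invariant under monotone transforms of the input. Constant genes map to
#' all zeros with a warning.
#'
#' @param expr Samples x genes matrix (>= 3 samples).
#' @return Transformed matrix, per-gene mean ~0 and SD ~1.
#' @export
inverse_normal_transform <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3L) stop("need at least 3 samples")
  n <- nrow(expr)
  const <- apply(expr, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) warning(sum(const), " constant gene(s) set to zero scores")
  out <- apply(expr, 2L, function(v) {
    if (stats::sd(v) == 0) return(rep(0, n))
    stats::qnorm((rank(v, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  })
  dimnames(out) <- dimnames(expr)
  out
}

# weighted, centered columns with unit weighted norm (bicor building block);
# columns with zero MAD fall back to Pearson standardization
.bicor_cols <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  fallback <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    med <- stats::median(v)
    madv <- stats::mad(v, constant = 1)
    if (madv == 0) {
      fallback[j] <- TRUE
      a <- v - mean(v)
    } else {
      u <- (v - med) / (9 * madv)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      a <- (v - med) * w
    }
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) stop("constant vector: correlation undefined")
    out[, j] <- a / nrm
  }
  if (warn && any(fallback))
    warning(sum(fallback), " vector(s) with zero MAD fell back to Pearson")
  out
}

#' Biweight midcorrelation
#'
#' Robust correlation: values are centered at the median, downweighted by
#' `(1 - u^2)^2` with `u = (x - median) / (9 * MAD)` (weight zero beyond
#' `|u| >= 1`), and the weighted cross-product is normalized by the weighted
#' norms. Vectors with zero MAD fall back to Pearson with a warning.
#'
#' @param x Numeric vector, or samples x genes matrix.
#' @param y Second vector (ignored when `x` is a matrix).
#' @return Correlation in `[-1, 1]`, or the gene x gene correlation matrix.
#' @export
bicor <- function(x, y = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (nrow(x) < 4L) stop("need at least 4 samples")
    a <- .bicor_cols(x)
    r <- crossprod(a)
    r[r > 1] <- 1; r[r < -1] <- -1
    return(r)
  }
  stopifnot(!is.null(y), length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 samples")
  a <- .bicor_cols(cbind(x, y))
  min(1, max(-1, sum(a[, 1] * a[, 2])))
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power the unsigned adjacency is `|cor|^power`, the
#' connectivity `k_i` is the off-diagonal row sum, and the scale-free
#' topology index is the signed R^2 of `log10 freq(k)` on `log10 k` over
#' ~`n_bins` bins (negated when the slope is positive). Returns the smallest
#' power whose index reaches `r2_target`, else the power maximizing the
#' index with a warning.
#'
#' @param cor_mat Gene x gene correlation matrix.
#' @param powers Candidate powers (default 1:20).
#' @param r2_target Scale-free index target (default 0.9).
#' @param n_bins Histogram bins for the degree distribution (default 10).
#' @return List: `power`, `fit_table` (power, r_squared, slope, mean_k).
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:20, r2_target = 0.9,
                                n_bins = 10) {
  ac <- abs(as.matrix(cor_mat))
  stopifnot(all(powers > 0))
  rows <- lapply(powers, function(p) {
    adj <- ac^p; diag(adj) <- 0
    k <- colSums(adj)
    if (stats::sd(k) == 0) {
      warning("degenerate connectivity at power ", p, "; index undefined")
      return(data.frame(power = p, r_squared = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    }
    br <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3L)
      return(data.frame(power = p, r_squared = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2L]
    data.frame(power = p, r_squared = ifelse(slope < 0, r2, -r2),
               slope = unname(slope), mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= r2_target)
  if (length(hit)) power <- tab$power[hit[1L]]
  else {
    power <- tab$power[which.max(tab$r_squared)]
    warning("no power reaches scale-free index ", r2_target,
            "; returning the best (", power, ")")
  }
  list(power = power, fit_table = tab)
}

#' Unsigned soft-thresholded adjacency
#'
#' `|cor|^power` with zero diagonal.
#'
#' @param cor_mat Gene x gene correlation matrix.
#' @param power Soft-threshold power (default 8).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(cor_mat, power = 8) {
  adj <- abs(as.matrix(cor_mat))^power
  diag(adj) <- 0
  adj
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i` the row sum; diagonal 1.
#'
#' @param adjacency Symmetric matrix in `[0, 1]` with zero diagonal.
#' @return Symmetric TOM in `[0, 1]`.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0) || any(a > 1)) stop("adjacency must lie in [0, 1]")
  if (any(diag(a) != 0)) { diag(a) <- 0 }
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  l <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

#' Detect modules by average-linkage clustering of the TOM
#'
#' Hierarchical clustering (average linkage) on the dissimilarity `1 - TOM`
#' with a static cut at `cut_height`; clusters smaller than
#' `min_module_size` are labeled `"unassigned"`. Remaining modules are
#' labeled `"M1", "M2", ...` in decreasing size (ties by first gene).
#'
#' @param tom TOM from [tom_matrix()].
#' @param min_module_size Minimum module size (default 5).
#' @param cut_height Static cut height on `1 - TOM` (default 0.995).
#' @return Named character vector of module labels per gene.
#' @export
detect_modules <- function(tom, min_module_size = 5, cut_height = 0.995) {
  tom <- as.matrix(tom)
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size)
    return(stats::setNames(rep("unassigned", nrow(tom)), genes))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("unassigned", length(cl))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) lab[cl == ord[i]] <- paste0("M", i)
  }
  stats::setNames(lab, genes)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized gene submatrix,
#' sign-aligned to correlate positively with the module's mean expression
#' profile and scaled to unit variance. Modules whose submatrix is singular
#' fall back to the (standardized) mean profile with a warning. The
#' `"unassigned"` label is skipped.
#'
#' @param expr Samples x genes expression (standardized per gene inside).
#' @param module_labels Named labels from [detect_modules()].
#' @return Samples x modules eigengene matrix.
#' @export
eigengene <- function(expr, module_labels) {
  expr <- as.matrix(expr)
  mods <- setdiff(sort(unique(module_labels)), "unassigned")
  if (!length(mods)) stop("no modules to summarize")
  out <- matrix(NA_real_, nrow(expr), length(mods),
                dimnames = list(rownames(expr), mods))
  for (m in mods) {
    g <- names(module_labels)[module_labels == m]
    g <- intersect(g, colnames(expr))
    if (length(g) < 2L) stop("module ", m, " has fewer than 2 genes")
    x <- scale(expr[, g, drop = FALSE])
    x[is.nan(x)] <- 0
    sv <- tryCatch(svd(x, nu = 1, nv = 0), error = function(e) NULL)
    if (is.null(sv) || sv$d[1L] == 0) {
      warning("singular module ", m, "; falling back to mean profile")
      pc <- rowMeans(x)
    } else {
      pc <- sv$u[, 1L] * sv$d[1L]
    }
    mp <- rowMeans(x)
    if (stats::sd(pc) == 0) pc <- mp
    if (sum(pc * mp) < 0) pc <- -pc
    out[, m] <- as.numeric(scale(pc))
  }
  out
}

#' Module-trait correlations
#'
#' Pearson correlation (two-sided test) between each eigengene and each
#' phenotype, with pairwise-complete observations and Benjamini-Hochberg FDR
#' across all module x trait pairs; significant iff `q < fdr`.
#'
#' @param eigengenes Samples x modules matrix.
#' @param phenotypes Samples x traits data.frame or matrix (numeric columns
#'   used; constant traits are excluded with a warning).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame: `module`, `trait`, `r`, `p_value`, `fdr_q`,
#'   `significant`.
#' @export
module_trait <- function(eigengenes, phenotypes, fdr = 0.05) {
  eg <- as.matrix(eigengenes)
  ph <- as.data.frame(phenotypes)
  ph <- ph[vapply(ph, is.numeric, TRUE)]
  drop <- vapply(ph, function(v) stats::sd(v, na.rm = TRUE) == 0, TRUE)
  if (any(drop)) {
    warning("constant trait(s) excluded: ", paste(names(ph)[drop], collapse = ", "))
    ph <- ph[!drop]
  }
  if (!ncol(ph)) stop("no usable traits")
  rows <- list()
  for (m in colnames(eg)) for (tr in names(ph)) {
    ok <- stats::complete.cases(eg[, m], ph[[tr]])
    if (sum(ok) < 4L) stop("fewer than 4 complete samples for ", m, " x ", tr)
    ct <- stats::cor.test(eg[ok, m], ph[[tr]][ok], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, trait = tr, r = unname(ct$estimate), p_value = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr_q < fdr
  out
}

#' Module membership (kME) and gene-trait correlations
#'
#' `kME(gene, module)` is the Pearson correlation between the gene's profile
#' and the module eigengene; gene-trait correlations are emitted alongside
#' so membership strength can be compared with trait association per gene.
#'
#' @param expr Samples x genes expression.
#' @param eigengenes Samples x modules eigengene matrix.
#' @param phenotypes Optional samples x traits table.
#' @return List: `kme` (genes x modules), `gene_trait` (genes x traits or
#'   NULL).
#' @export
module_membership <- function(expr, eigengenes, phenotypes = NULL) {
  expr <- as.matrix(expr)
  kme <- suppressWarnings(stats::cor(expr, as.matrix(eigengenes)))
  gt <- NULL
  if (!is.null(phenotypes)) {
    ph <- as.data.frame(phenotypes)
    ph <- ph[vapply(ph, is.numeric, TRUE)]
    gt <- suppressWarnings(stats::cor(expr, as.matrix(ph),
                                      use = "pairwise.complete.obs"))
  }
  list(kme = kme, gene_trait = gt)
}

#' Intramodular connectivity
#'
#' `k_within(g)` = sum of `g`'s adjacencies to the other genes sharing its
#' module label. Unassigned genes are summed over the unassigned set and
#' flagged.
#'
#' @param adjacency Gene x gene adjacency (zero diagonal).
#' @param module_labels Named labels covering all genes.
#' @return data.frame: `gene`, `module`, `k_within`, `unassigned`.
#' @export
k_within <- function(adjacency, module_labels) {
  a <- as.matrix(adjacency)
  genes <- rownames(a) %||% names(module_labels)
  stopifnot(length(module_labels) == nrow(a))
  lab <- module_labels[genes]
  kw <- vapply(seq_along(genes), function(i) {
    same <- which(lab == lab[i])
    sum(a[i, setdiff(same, i)])
  }, numeric(1))
  data.frame(gene = genes, module = unname(lab), k_within = kw,
             unassigned = unname(lab == "unassigned"), row.names = NULL)
}

#' Normalized differential connectivity
#'
#' `kdiff = (k_a - k_b) / (k_a + k_b)`, in `[-1, 1]` whenever
#' `k_a + k_b > 0`; positive values mean more connectivity in the first
#' cohort. `NA` when both connectivities are zero.
#'
#' @param k_a,k_b Non-negative intramodular connectivities.
#' @return kdiff values.
#' @export
kdiff <- function(k_a, k_b) {
  s <- k_a + k_b
  ifelse(s > 0, (k_a - k_b) / s, NA_real_)
}

#' Differential connectivity between two cohorts
#'
#' Recomputes the adjacency per cohort from that cohort's samples (biweight
#' midcorrelation at the shared `power`) and the intramodular connectivity
#' under the SHARED module labels from the all-sample network, then
#' `kdiff = (k_a - k_b)/(k_a + k_b)`. A gene is flagged differentially
#' connected iff `|kdiff| > threshold` strictly; genes with zero
#' connectivity in both cohorts are returned with `k_diff = NA` and flagged
#' `undefined`.
#'
#' @param expr_a,expr_b Samples x genes expression for the two cohorts
#'   (same genes; >= 4 samples each).
#' @param module_labels Shared module labels (named by gene).
#' @param power Soft-threshold power (default 8).
#' @param threshold Flagging threshold on `|kdiff|` (default 0.5).
#' @return data.frame: `gene`, `module`, `k_a`, `k_b`, `k_diff`, `flagged`,
#'   `undefined`.
#' @export
differential_connectivity <- function(expr_a, expr_b, module_labels,
                                      power = 8, threshold = 0.5) {
  expr_a <- as.matrix(expr_a); expr_b <- as.matrix(expr_b)
  if (nrow(expr_a) < 4L || nrow(expr_b) < 4L)
    stop("each cohort needs at least 4 samples")
  if (!identical(colnames(expr_a), colnames(expr_b)))
    stop("cohorts must share the same gene set")
  ka <- k_within(adjacency_matrix(suppressWarnings(bicor(expr_a)), power),
                 module_labels)
  kb <- k_within(adjacency_matrix(suppressWarnings(bicor(expr_b)), power),
                 module_labels)
  kd <- kdiff(ka$k_within, kb$k_within)
  data.frame(gene = ka$gene, module = ka$module,
             k_a = ka$k_within, k_b = kb$k_within, k_diff = kd,
             flagged = !is.na(kd) & abs(kd) > threshold,
             undefined = is.na(kd), row.names = NULL)
}

#' Network edge list
#'
#' Long-format upper-triangle edge list of an adjacency matrix, filtered by
#' a minimum weight, for export to network-visualization tools.
#'
#' @param adjacency Gene x gene adjacency.
#' @param min_weight Minimum edge weight retained (default 0).
#' @return data.frame: `gene1`, `gene2`, `weight`.
#' @export
edge_list <- function(adjacency, min_weight = 0) {
  a <- as.matrix(adjacency)
  genes <- rownames(a) %||% paste0("g", seq_len(nrow(a)))
  idx <- which(upper.tri(a) & a >= min_weight & a > 0, arr.ind = TRUE)
  data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
             weight = a[idx], row.names = NULL)
}
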