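# shared fixtures and small oracles built in code

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# contribution tables straight from fitted cell-type models
contributions_from_fits <- function(fits) {
  tabs <- lapply(names(fits$expected), function(co)
    contribution_table(fits$expected[[co]], fits$cell_counts[[co]]))
  stats::setNames(tabs, names(fits$expected))
}

# brute-force TOM by double loop (independent of the matrix-product path)
tom_brute <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# toy QC counts matrix: 6 cells violating one criterion each + 1 clean cell
qc_toy <- function() {
  n_genes <- 3500
  genes <- c("mt-Nd1", paste0("gene", seq_len(n_genes - 1)))
  mk <- function(n_feature, total, mito = 0) {
    x <- numeric(n_genes)
    stopifnot(n_feature <= n_genes - 1)
    per <- floor((total - mito) / n_feature)
    x[1 + seq_len(n_feature)] <- per
    x[2] <- x[2] + (total - mito) - per * n_feature
    x[1] <- mito
    x
  }
  m <- rbind(
    clean      = mk(1500, 5000),
    feat_low   = mk(499, 2000),
    feat_high  = mk(3100, 6200),
    count_low  = mk(800, 900),
    count_high = mk(1500, 31000),
    mito_high  = mk(1500, 5000, mito = 2000),
    feat_edge  = mk(3001, 9003)
  )
  colnames(m) <- genes
  m
}
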