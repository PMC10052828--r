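# Wilcoxon rank-sum marker detection between cell groups.

#' Rank-sum marker detection between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction), average log fold change as the difference of group means of
#' the log-normalized values, and the fraction of cells expressing the gene
#' per group. A gene is significant when the focal group is the
#' higher-expressing one (`avg_log_fc >= lfc_min`), at least `min_pct` of
#' cells in one group express it, and the Bonferroni-adjusted p-value (the
#' multiplier is the number of genes tested) is below `alpha`.
#'
#' @param expr Cells x genes log-normalized expression.
#' @param labels Per-cell group labels.
#' @param group_a,group_b Labels of the focal and reference groups.
#' @param lfc_min Minimum average log fold change (natural log; default 0.25).
#' @param min_pct Minimum expressing fraction in either group (default 0.25).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param correction Multiple-testing correction; only `"bonferroni"`.
#' @return data.frame: `gene`, `avg_log_fc`, `pct_a`, `pct_b`, `p_value`,
#'   `p_adjusted`, `significant`, ordered by p-value.
#' @export
rank_sum_markers <- function(expr, labels, group_a, group_b,
                             lfc_min = 0.25, min_pct = 0.25, alpha = 0.01,
                             correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  stopifnot(nrow(expr) == length(labels))
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(ia) < 3L || length(ib) < 3L)
    warning("a group has fewer than 3 cells; p-values may be degenerate")
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  G <- length(genes)
  p <- numeric(G); lfc <- numeric(G); pa <- numeric(G); pb <- numeric(G)
  for (j in seq_len(G)) {
    xa <- expr[ia, j]; xb <- expr[ib, j]
    lfc[j] <- mean(xa) - mean(xb)
    pa[j] <- mean(xa > 0); pb[j] <- mean(xb > 0)
    p[j] <- if (stats::sd(c(xa, xb)) == 0) 1
    else suppressWarnings(
      stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
  }
  p_adj <- pmin(1, p * G)
  sig <- lfc >= lfc_min & pmax(pa, pb) >= min_pct & p_adj < alpha
  out <- data.frame(gene = genes, avg_log_fc = lfc, pct_a = pa, pct_b = pb,
                    p_value = p, p_adjusted = p_adj, significant = sig,
                    row.names = NULL)
  attr(out, "lfc_convention") <- "difference of mean log-normalized values (base e)"
  out[order(out$p_value), , drop = FALSE]
}

#' Per-subtype overexpressed gene profiles (one-vs-rest)
#'
#' Runs [rank_sum_markers()] for each subtype against all other cells of the
#' parent population, with the subtype thresholds (log-FC >= 0.1, Bonferroni
#' adjusted p < 0.01 by default). Singleton subtypes are skipped with a
#' warning. A gene may appear in several subtype sets.
#'
#' @param expr Cells x genes log-normalized expression (parent population).
#' @param subtype_labels Per-cell subtype labels.
#' @param lfc_min,alpha,min_pct Thresholds (defaults 0.1, 0.01, 0).
#' @return Named list per subtype: `table` (full marker table) and `markers`
#'   (character vector of significant, overexpressed genes).
#' @export
subtype_profiles <- function(expr, subtype_labels, lfc_min = 0.1,
                             alpha = 0.01, min_pct = 0) {
  subs <- sort(unique(subtype_labels))
  if (length(subs) < 2L) stop("need at least 2 subtypes")
  out <- list()
  for (s in subs) {
    if (sum(subtype_labels == s) < 2L) {
      warning("subtype ", s, " is a singleton; skipped")
      next
    }
    lab <- ifelse(subtype_labels == s, s, ".rest")
    tab <- rank_sum_markers(expr, lab, s, ".rest",
                            lfc_min = lfc_min, min_pct = min_pct, alpha = alpha)
    out[[s]] <- list(table = tab, markers = tab$gene[tab$significant])
  }
  out
}
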