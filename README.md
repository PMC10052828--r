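# isletdecon

Cell-type attribution of pancreatic-islet gene expression, and downstream
co-expression network analysis, for integrated single-cell + bulk RNA-seq
studies.

Bulk islet RNA-seq mixes signal from β-cells, other endocrine cell types,
and exocrine contamination. `isletdecon` asks, per gene: *how much of the
bulk signal comes from β-cells?* — and restricts downstream analyses (bulk
differential comparisons, co-expression modules, trait correlations) to the
genes where that share is high enough, in every cohort, to read bulk changes
as β-cell changes.

## The model

Single-cell expression of a gene within a cell type, rescaled to the unit
interval, is described by a **beta-hurdle model** with three parameters
(Pr(Dropout), α, β): a point mass at zero plus a Beta(α, β) component for
expressing cells. The pieces are fit separately:

1. **Shapes by minimum KS distance** (maximum goodness-of-fit): (α, β)
   minimize the sup-distance between the empirical CDF of nonzero values
   and the Beta(α, β) CDF, via a log-spaced grid refined by Nelder–Mead.
2. **Dropout by iteration**: Pr(Dropout) = d is scanned over [0, 1] in steps
   of 0.01; a fraction *d* of observed zeros is attributed to technical
   non-detection, the rest stay as true zeros, and the *d* minimizing the KS
   distance of the retained sample is selected (ties toward larger *d*).

The expected expression per cell type is the beta mean,

    E[Y_ct] = 1 / (1 + β/α) = α / (α + β),

and a cell type's **relative contribution** to a gene's total expression is

    Q_ct = E[Y_ct] · N_ct / Σ_ct' E[Y_ct'] · N_ct' ,

with N_ct the number of cells of that type. A gene is called
**β-cell-specific** when Q_β ≥ τ (default 0.8) in *every* cohort.

Around this core the package provides: cell-level QC (closed-range
feature/count/mito filters and a 3-SD residual filter on the nCount–nFeature
line) and log-normalization; Wilcoxon rank-sum marker detection with
log-FC/percent-expressed/Bonferroni gates; bootstrap subtype-composition
estimates with percentile CIs and CI-overlap comparisons; a permutation test
for gene-set overlap with an exact hypergeometric oracle; islet phenotype
derivation (GSIS, basal secretion, insulin content); and a weighted
co-expression network stage (TMM via edgeR, rank-based inverse normal
transform, biweight midcorrelation, unsigned soft-thresholded adjacency,
topological overlap, average-linkage modules, eigengenes, module–trait FDR,
and differential connectivity kDiff = (k_A − k_B)/(k_A + k_B) with |kDiff| >
0.5 flagged). A synthetic-data module generates single-cell and bulk
datasets with full ground truth, so every stage is testable end to end.

## Worked example

```r
library(isletdecon)

study <- simulate_islet_study(n_genes = 30, n_specific = 5, seed = 42)
cells <- generate_cells(study$specs, study$cohorts, seed = 42)
fits  <- fit_cell_type_models(cells$matrix, cells$cell_meta)
tabs  <- lapply(names(fits$expected), function(co)
  contribution_table(fits$expected[[co]], fits$cell_counts[[co]]))
names(tabs) <- names(fits$expected)
calls <- call_specific_genes(tabs, target = "beta", tau = 0.8)
head(calls[, c("gene_id", "Q_HM20", "Q_HM30", "min_q", "called")], 7)
#>     gene_id Q_HM20 Q_HM30 min_q called
#> 1  gene_001  1.000  1.000 1.000   TRUE
#> 2  gene_002  1.000  1.000 1.000   TRUE
#> 3  gene_003  1.000  1.000 0.981   TRUE
#> 5  gene_005  0.975  1.000 0.975   TRUE
#> 4  gene_004  1.000  1.000 0.968   TRUE
#> 9  gene_009  0.276  0.267 0.267  FALSE
#> 12 gene_012  0.283  0.267 0.267  FALSE
```

`Q_<cohort>` is the β-cell share of the gene's modeled total expression in
that cohort; `min_q` is the worst share across the six cohorts, and `called`
marks genes clearing τ = 0.8 everywhere. The five planted β-specific genes
are recovered with no false calls (`sum(calls$called)` is 5 of 30). Whether
that recovered set is enriched in an independent gene set is then a
permutation question:

```r
ot <- overlap_permutation_test(calls$gene_id[calls$called],
                               study$truth$specific_genes,
                               cells$gene_ids, n_perm = 1000, seed = 1)
sprintf("observed overlap %d, permutation p = %.3g", ot$observed, ot$p_value)
#> "observed overlap 5, permutation p = 0.000999"
```

(p = 1/(n_perm + 1), the smallest value the add-one estimator can return.)

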