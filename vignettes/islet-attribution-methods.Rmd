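---
title: "Attributing islet gene expression to cell types: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing islet gene expression to cell types: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletdecon)
```

## The problem

Bulk RNA-seq of pancreatic islets averages over β-cells, other endocrine
types (α, δ, PP), and exocrine contamination, while single-cell RNA-seq
resolves cell types but is noisy at the level of individual genes and
cells. `isletdecon` integrates the two: it uses the single-cell data to
model, per gene and per cell type, how much of the total expression each
cell type contributes, and carries only the genes dominated by β-cells into
bulk-level analyses. Downstream changes in those genes can then be read as
β-cell changes rather than shifts in tissue composition.

## The beta-hurdle model

Within one cohort, a gene's per-cell expression values in a cell type are
rescaled to the open unit interval by dividing by the cohort-wide per-gene
maximum times $(1+\varepsilon)$, $\varepsilon = 10^{-6}$. The shared scale
across cell types within a cohort matters: expected values feed a ratio
across cell types, and per-type rescaling would distort it. The rescaling
is monotone and scale-free, so it preserves relative structure; zeros stay
zero.

The rescaled values are modeled as a hurdle: a point mass at zero plus a
$\mathrm{Beta}(\alpha,\beta)$ component for expressing cells.

**Shape fitting.** $(\alpha,\beta)$ are chosen by minimum-distance
(maximum goodness-of-fit) estimation: they minimize the two-sided
Kolmogorov–Smirnov distance between the empirical CDF of the nonzero
values and the beta CDF. The search combines a $10\times10$ log-spaced
grid over $[0.01, 100]^2$ (always including the uniform candidate
$(1,1)$) with Nelder–Mead refinement from the best grid point; the
returned distance never exceeds that of any evaluated candidate. KS
minimization is preferred to maximum likelihood here because single-cell
expression after normalization is only approximately beta; the KS
objective targets global CDF agreement and is insensitive to density
spikes near the support boundary that destabilize the beta likelihood.
The moment diagnostic `cullen_frey_diagnostic()` (squared skewness vs
kurtosis with a bootstrap cloud, and the beta-feasible band between
$k = s^2 + 1$ and $k = 3 + 1.5 s^2$) is provided to check that the beta
family is a reasonable home for a given gene before fitting.

**Dropout iteration.** Observed zeros conflate true non-expression with
technical dropout. $\Pr(\mathrm{Dropout}) = d$ is scanned over a grid on
$[0,1]$ (step 0.01): a fraction $d$ of the observed zeros is treated as
non-detections carrying no information about the expression law and
excluded, the remaining zeros stay in the sample as true non-expressors,
and the KS distance between the retained sample and the fitted beta law is
evaluated. The selected $d$ minimizes this distance, with ties broken
toward larger $d$. Retained zeros are misfit mass against a distribution
of expressing cells, so when the nonzero values are well described by the
beta — the typical case — the fit improves monotonically as more zeros are
attributed to dropout and $d = 1$ is selected; a formulation that instead
matches a zero atom against the full empirical CDF degenerates to $d = 0$
for every gene and cannot reproduce this behavior. The model's mixture CDF
with true-zero mass $\pi_0 = \text{zero fraction} \cdot (1-d)$ is exposed
as `hurdle_cdf()`.

Fits are skipped (with a low-support flag) below 20 nonzero cells; such
strata contribute zero expected value. The grid step 0.01 and the support
floor bound both runtime and estimator variance; both are configurable.

**Expected values and contributions.** The default expected value is the
plain beta mean $E[Y] = 1/(1+\beta/\alpha) = \alpha/(\alpha+\beta)$,
applied unconditionally; a mixture-corrected variant
$(1-\pi_0)\,\alpha/(\alpha+\beta)$ is available behind a flag and
coincides with the default when all zeros are attributed to dropout. Each
cell type's contribution to a gene is $E[Y_{ct}] \cdot N_{ct}$ and its
share $Q_{ct}$ is that term over the sum across types; shares sum to one
by construction. A gene is called β-cell-specific when $Q_\beta \ge \tau$
(default 0.8) in **every** cohort — an intersection rule, so one
discordant cohort vetoes the call. Fitting is done per cohort because the
threshold is applied per cohort.

## Quality control and normalization

Cells pass QC when detected features (500–3000), total counts
(1000–30,000), and percent mitochondrial counts (0–30) all fall inside
closed ranges (closed because the interval notation does not indicate
openness; the boundary cell at 499 features is excluded either way).
Afterwards, an OLS line of features on counts is fit to the survivors and
cells whose residual exceeds 3 SDs are dropped — cells whose library size
does not predict their complexity. The SD uses the $n-1$ denominator, a
convention that must simply be fixed for reproducibility. Percent
mitochondrial counts is defined as 0 for a zero-count cell so the report
never contains NaN. Normalization is per-cell library-size scaling on the
natural-log scale, $\log(1 + 10^4 \cdot c/\text{total})$.

## Markers, composition, overlap

**Markers** use a two-sided Wilcoxon rank-sum test (normal approximation
with tie correction) per gene; the average log fold change is the
difference of group means of log-normalized values (base e; this simple
convention is recorded in the output rather than the exponentiated-mean
variant some toolkits use), and calls additionally require the focal group
to be higher-expressing and the gene detected in at least a minimum
fraction of one group. Cell-type contrasts default to log-FC ≥ 0.25 with
25% detection; subtype one-vs-rest profiles default to log-FC ≥ 0.1 and
Bonferroni-adjusted p < 0.01. All in-package differential expression uses
this Wilcoxon path; hurdle-model DE testers published elsewhere are
deliberately not re-implemented.

**Composition** per cohort is estimated by bootstrap: the point estimate is
the observed subtype fraction over all cells, and each of 100 iterations
draws 1,000 cells with replacement (also when the cohort is smaller, which
keeps the procedure defined everywhere); the 95% CI is the percentile
interval with linear interpolation between order statistics. Two cohorts
differ significantly in a subtype when their CIs are strictly disjoint —
touching endpoints do not count. Percentile intervals are distribution-free
and may exclude the point estimate in tiny samples; that is expected
behavior, not an error.

**Overlap** between a called gene set and a reference set is tested by
permutation: the reference set's size is redrawn uniformly from the
universe (all genes in the single-cell dataset by default) 1,000 times,
and the add-one estimator $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$
avoids zero p-values. By symmetry of the hypergeometric law it does not
matter which of the two sets is resampled. An exact tail sum
(`hypergeometric_tail()`) serves as the oracle the permutation test is
validated against.

## Co-expression networks

Bulk counts restricted to the specific genes are TMM-normalized (delegated
to edgeR) and transformed gene-wise to standard-normal scores by the
rank-based inverse normal transform with the Blom offset
$(r - 3/8)/(n + 1/4)$ — "converted to standard normal" is read
distributionally, not as z-scoring; a z-score mode exists behind the
transform's rank-free fallback for constant genes. The adjacency is the
unsigned soft-thresholded biweight midcorrelation $|bicor|^{8}$; power 8
is the package default, and `pick_soft_threshold()` reproduces the
scale-free index (signed $R^2$ of the log–log degree fit over ~10 bins)
used to justify it. Biweight midcorrelation downweights samples beyond 9
robust MADs from the median and falls back to Pearson when the MAD
degenerates (logged) — relevant for small cohort subsets.

Modules are detected by average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$ with a **static** cut at 0.995 and a minimum size of 5;
dynamic tree-cut heuristics are intentionally replaced by a deterministic
cut because the validation surface is planted-partition recovery, not
bit-compatibility with any particular toolkit. Eigengenes are first
principal components of standardized module submatrices, sign-aligned to
the module mean profile and unit-variance scaled. Module–trait
relationships are Pearson correlations with Benjamini–Hochberg FDR across
all module × trait pairs (BH being the default reading of "FDR-corrected"),
significant at q < 0.05.

Intramodular connectivity $k_{within}$ sums a gene's **adjacency** (not
TOM) to the other genes of its module. For differential connectivity the
adjacency is recomputed per cohort from that cohort's samples, under the
shared all-sample module labels, and
$kDiff = (k_A - k_B)/(k_A + k_B) \in [-1, 1]$; $|kDiff| > 0.5$ — strictly —
flags a gene, and genes disconnected in both cohorts are reported as
undefined rather than forced to zero.

## The synthetic-data generator

The generator exists so every stage can be validated against known truth.
It emulates: per-gene per-cell-type hurdle-beta expression (point mass
plus clipped beta draws, support kept open by $\varepsilon = 10^{-6}$);
cohort-specific cell counts and β-subtype proportions, with subtypes
implemented as β-cell sub-labels that may override gene parameters (which
is what makes marker and composition recovery testable); bulk samples as
cell-count-weighted sums of analytic beta means under multiplicative
lognormal noise with a chosen CV — the link between single-cell totals and
bulk counts is approximate in nature and no noise law is dictated by it,
so the lognormal-CV choice is ours; a flat exocrine contamination share;
and planted co-expression modules whose genes share a latent per-sample
factor that may tilt a phenotype linearly (phenotype noise is Gaussian,
the simplest testable choice). Dropout and true zeros are generated
identically — both are observed zeros — because the observable data cannot
distinguish them; the generating attribution is recorded in the truth
object for recovery tests only.

What it does **not** emulate: read-level sequencing artifacts, UMI
chemistry, ambient-RNA structure beyond the flat share, batch effects,
doublets, or cell-type misassignment. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to all failure modes of real single-cell data.

## Validation scales and numerical choices

The test suite validates, among others: shape recovery (50 genes across
the $\{0.5, 2, 5\}^2$ shape grid, 2,000 cells, 30% dropout; median
relative error well under 15%, dropout attributed at $d \ge 0.9$
throughout); specific-gene recovery in a 6-cohort, 4-type, 50-gene study
with 10 planted β-specific genes (sensitivity and specificity at or near
1); bootstrap CI coverage near nominal over 100 replicate cohorts of
5,000 cells; permutation p-values within Monte-Carlo error of the exact
hypergeometric tail across 20 configurations; planted-module recovery
(32 samples, 300 genes, 3 modules at within-correlation 0.8) with
adjusted Rand ≥ 0.8 and the trait-linked module flagged at q < 0.05 in
≥ 90% of 20 seeds; and TOM agreement with a brute-force double loop to
$10^{-12}$. These sizes were chosen as the smallest at which the
statistical properties are stable; all are parameters of the test code,
not of the package.

Numerical conventions worth knowing: empirical CDFs are right-continuous
and the KS distance is evaluated on both sides of each jump; beta draws
are clipped to $[\varepsilon, 1-\varepsilon]$; dropout-grid ties break
toward $d = 1$; `call_specific_genes` sorts by worst-cohort share;
degenerate inputs (all-zero genes, constant vectors, zero-count cells,
singleton modules, zero denominators) return flagged results or typed
errors rather than NaNs.

## Limitations

The attribution inherits the model's assumptions: cell counts stand in
for mRNA mass (no per-type capture-efficiency correction), the beta mean
is used unconditionally rather than weighted by detection, and clusters
enter as fixed labels — uncertainty in cell typing does not propagate.
With four samples per cohort, cohort-specific correlation estimates are
noisy and kDiff should be read as a screen, not a test; no significance
is attached to it. The module detector's static cut trades adaptivity for
determinism and can split or absorb modules whose within-correlation is
far from the validated regime.
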