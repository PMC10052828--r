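# Synthetic single-cell + bulk islet data with full ground truth.
#
# The generator mirrors the statistical structure the downstream analysis
# assumes: per gene x cell type, expression on the unit interval follows a
# hurdle-beta law (point mass at zero plus a Beta(alpha, beta) draw); cohorts
# carry their own cell counts and subtype proportions; bulk samples are
# cell-count-weighted sums of per-type expected values with multiplicative
# lognormal noise, optional exocrine contamination, and planted co-expression
# modules that may be linked to phenotypes.

#' Cohort specification
#'
#' Describes one age x diet x sex cohort: how many cells of each type it
#' contains, the subtype mix of the parent (beta) cell population, how many
#' bulk samples to simulate, and cohort-level phenotype means.
#'
#' @param cohort_id Cohort label, e.g. `"HM20"` (20-week high-fat males).
#' @param n_cells_per_type Named non-negative integer vector, cells per type.
#' @param subtype_proportions Optional named numeric vector of beta-cell
#'   subtype proportions; must sum to 1 (tolerance 1e-9).
#' @param n_bulk_samples Number of bulk RNA-seq samples for this cohort.
#' @param trait_means Optional named numeric vector of phenotype means
#'   (e.g. blood glucose, GSIS) around which sample traits are drawn.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, n_cells_per_type,
                        subtype_proportions = NULL,
                        n_bulk_samples = 4L, trait_means = NULL) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  if (is.null(names(n_cells_per_type)) || any(!nzchar(names(n_cells_per_type))))
    stop("n_cells_per_type must be a named vector of cell types")
  if (any(n_cells_per_type < 0))
    stop("cell counts must be >= 0")
  if (!is.null(subtype_proportions)) {
    if (is.null(names(subtype_proportions)))
      stop("subtype_proportions must be named")
    if (abs(sum(subtype_proportions) - 1) > 1e-9)
      stop("subtype proportions must sum to 1 (cohort ", cohort_id, ")")
    if (any(subtype_proportions < 0))
      stop("subtype proportions must be non-negative")
  }
  structure(list(cohort_id = cohort_id,
                 n_cells_per_type = stats::setNames(
                   as.integer(round(n_cells_per_type)), names(n_cells_per_type)),
                 subtype_proportions = subtype_proportions,
                 n_bulk_samples = as.integer(n_bulk_samples),
                 trait_means = trait_means),
            class = "cohort_spec")
}

#' Gene specification table
#'
#' Validates a long-format table of hurdle-beta parameters per gene and cell
#' type (or beta-cell subtype override). Columns: `gene_id`, `cell_type`,
#' `alpha`, `beta_` (beta-distribution shapes), `pi0` (true-zero point mass),
#' `pr_dropout` (intended share of observed zeros attributable to dropout,
#' recorded in the truth object only -- dropout and true zeros are
#' observationally identical).
#'
#' @param specs data.frame with the columns above.
#' @return The validated data.frame (invisibly classed `gene_specs`).
#' @export
gene_specs <- function(specs) {
  need <- c("gene_id", "cell_type", "alpha", "beta_", "pi0", "pr_dropout")
  miss <- setdiff(need, names(specs))
  if (length(miss)) stop("gene_specs missing columns: ", paste(miss, collapse = ", "))
  if (any(specs$alpha <= 0) || any(specs$beta_ <= 0))
    stop("beta shape parameters must be positive")
  if (any(specs$pi0 < 0 | specs$pi0 > 1) || any(specs$pr_dropout < 0 | specs$pr_dropout > 1))
    stop("pi0 and pr_dropout must lie in [0, 1]")
  if (anyDuplicated(specs[, c("gene_id", "cell_type")]))
    stop("duplicate (gene_id, cell_type) rows in gene specs")
  class(specs) <- unique(c("gene_specs", class(specs)))
  specs
}

# Beta variates clipped away from {0, 1} so the support stays open.
.SYNTH_EPS <- 1e-6

.rbeta_open <- function(n, a, b) {
  pmin(pmax(stats::rbeta(n, a, b), .SYNTH_EPS), 1 - .SYNTH_EPS)
}

# Parameter row lookup: subtype override wins over parent cell type.
.spec_row <- function(specs, gene, type, parent) {
  i <- which(specs$gene_id == gene & specs$cell_type == type)
  if (!length(i) && !is.null(parent))
    i <- which(specs$gene_id == gene & specs$cell_type == parent)
  if (length(i)) specs[i[1L], ] else NULL
}

#' Simulate annotated single-cell expression
#'
#' Draws a cell x gene matrix on the unit interval: each cell's value for a
#' gene is 0 with probability `pi0` and otherwise a Beta(alpha, beta) variate,
#' using the parameters for the cell's type (beta-cell subtypes may carry
#' their own parameter rows, e.g. for marker genes). Cells are labeled with
#' type, subtype, and cohort; the returned truth records every generating
#' parameter.
#'
#' @param specs A [gene_specs()] table.
#' @param cohorts List of [cohort_spec()] objects.
#' @param seed Integer seed; identical seeds yield identical datasets.
#' @param subtype_parent Cell type whose cells receive subtype labels
#'   (default `"beta"`).
#' @return A list of class `annotated_expression`: `matrix` (cells x genes),
#'   `cell_meta` (barcode, cell_type, subtype, cohort), `gene_ids`, `truth`.
#' @export
generate_cells <- function(specs, cohorts, seed, subtype_parent = "beta") {
  specs <- gene_specs(as.data.frame(specs))
  if (!length(cohorts)) stop("at least one cohort is required")
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  stopifnot(all(vapply(cohorts, inherits, TRUE, "cohort_spec")))
  genes <- unique(specs$gene_id)
  set.seed(as.integer(seed))

  meta_list <- list(); blocks <- list()
  for (co in cohorts) {
    types <- names(co$n_cells_per_type)
    for (ty in types) {
      n <- co$n_cells_per_type[[ty]]
      if (n == 0L) next
      sub <- rep(NA_character_, n)
      if (ty == subtype_parent && !is.null(co$subtype_proportions)) {
        sub <- sample(names(co$subtype_proportions), n, replace = TRUE,
                      prob = co$subtype_proportions)
      }
      meta_list[[length(meta_list) + 1L]] <-
        data.frame(cell_type = ty, subtype = sub, cohort = co$cohort_id,
                   stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_list)
  if (is.null(meta) || !nrow(meta)) stop("cohorts contain no cells")
  meta$barcode <- sprintf("cell_%06d", seq_len(nrow(meta)))
  meta <- meta[, c("barcode", "cell_type", "subtype", "cohort")]

  # effective parameter group: subtype label when overridden, else cell type
  eff <- ifelse(!is.na(meta$subtype), meta$subtype, meta$cell_type)
  mat <- matrix(0, nrow = nrow(meta), ncol = length(genes),
                dimnames = list(meta$barcode, genes))
  for (g in genes) {
    for (grp in unique(eff)) {
      idx <- which(eff == grp)
      parent <- if (grp %in% meta$cell_type) NULL else subtype_parent
      row <- .spec_row(specs, g, grp, parent)
      if (is.null(row)) next
      nz <- stats::runif(length(idx)) >= row$pi0
      vals <- numeric(length(idx))
      if (any(nz)) vals[nz] <- .rbeta_open(sum(nz), row$alpha, row$beta_)
      mat[idx, g] <- vals
    }
  }

  true_props <- lapply(cohorts, function(co) co$subtype_proportions)
  names(true_props) <- vapply(cohorts, `[[`, "", "cohort_id")
  truth <- list(gene_specs = specs, cohorts = cohorts,
                subtype_proportions = true_props,
                specific_genes = character(0),
                module_assignments = NULL, module_trait_links = NULL)
  structure(list(matrix = mat, cell_meta = meta, gene_ids = genes,
                 truth = truth),
            class = "annotated_expression")
}

# analytic E[Y] * N summed over (non-)exocrine types for one cohort
.cohort_terms <- function(specs, co, exocrine_types, genes) {
  types <- names(co$n_cells_per_type)
  endo <- numeric(length(genes)); exo <- numeric(length(genes))
  names(endo) <- names(exo) <- genes
  for (ty in types) {
    n <- co$n_cells_per_type[[ty]]
    if (n == 0L) next
    sel <- specs[specs$cell_type == ty & specs$gene_id %in% genes, ]
    if (!nrow(sel)) next
    ev <- sel$alpha / (sel$alpha + sel$beta_) * n
    if (ty %in% exocrine_types) exo[sel$gene_id] <- exo[sel$gene_id] + ev
    else endo[sel$gene_id] <- endo[sel$gene_id] + ev
  }
  list(endo = endo, exo = exo)
}

#' Simulate bulk expression and phenotypes
#'
#' Each cohort's expected bulk profile is the cell-count-weighted sum of the
#' per-type beta means, Sum_ct E[Beta(alpha, beta)] * N_ct. Per sample the
#' profile is perturbed by multiplicative lognormal noise with coefficient of
#' variation `noise_cv`; genes assigned to a planted module share a latent
#' per-sample factor (correlation `module_cor` on the log scale), and flagged
#' modules tilt a phenotype linearly through that factor. A
#' `contamination_fraction` share of each sample's total signal is
#' contributed by the designated exocrine cell types.
#'
#' @param specs A [gene_specs()] table.
#' @param cohorts List of [cohort_spec()] objects (uses `n_bulk_samples`,
#'   `trait_means`).
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of the lognormal noise (>= 0;
#'   0 gives the exact analytic sums).
#' @param contamination_fraction Share of total signal from exocrine types,
#'   in `[0, 1)`.
#' @param exocrine_types Character vector of cell types treated as exocrine
#'   contamination sources.
#' @param module_assignments Optional named vector/list mapping gene ->
#'   module id for planted co-expression.
#' @param module_cor Within-module correlation of log-scale noise.
#' @param module_trait_links Optional data.frame (module, phenotype, effect)
#'   linking planted modules to phenotypes; `effect` is the latent
#'   correlation in `[0, 1]`.
#' @param trait_sd Phenotype noise standard deviation.
#' @return List of class `bulk_dataset`: `counts` (samples x genes),
#'   `phenotypes` (data.frame, one row per sample), `truth`.
#' @export
generate_bulk <- function(specs, cohorts, seed, noise_cv = 0.2,
                          contamination_fraction = 0,
                          exocrine_types = character(0),
                          module_assignments = NULL, module_cor = 0.8,
                          module_trait_links = NULL, trait_sd = 1) {
  specs <- gene_specs(as.data.frame(specs))
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  stopifnot(noise_cv >= 0, contamination_fraction >= 0, contamination_fraction < 1)
  genes <- unique(specs$gene_id)
  set.seed(as.integer(seed))

  mod <- rep(NA_character_, length(genes)); names(mod) <- genes
  if (!is.null(module_assignments)) {
    ma <- unlist(module_assignments)
    mod[intersect(names(ma), genes)] <- ma[intersect(names(ma), genes)]
  }
  modules <- unique(stats::na.omit(mod))
  sigma <- sqrt(log(1 + noise_cv^2))

  links <- module_trait_links
  if (!is.null(links)) links <- as.data.frame(links)

  traits <- unique(c(unlist(lapply(cohorts, function(co) names(co$trait_means))),
                     if (!is.null(links)) as.character(links$phenotype)))

  rows <- list(); pheno <- list()
  for (co in cohorts) {
    terms <- .cohort_terms(specs, co, exocrine_types, genes)
    base <- terms$endo
    if (contamination_fraction > 0) {
      if (sum(terms$exo) <= 0)
        stop("contamination requested but no exocrine type contributes signal")
      base <- base + terms$exo / sum(terms$exo) *
        contamination_fraction / (1 - contamination_fraction) * sum(terms$endo)
    }
    for (s in seq_len(co$n_bulk_samples)) {
      z <- stats::setNames(stats::rnorm(length(modules)), modules)
      val <- base
      if (sigma > 0) {
        eps <- stats::rnorm(length(genes))
        lat <- ifelse(is.na(mod), 0, z[mod])
        shared <- ifelse(is.na(mod), 0, sqrt(module_cor))
        noise <- sigma * (shared * lat + sqrt(1 - shared^2) * eps) - sigma^2 / 2
        val <- base * exp(noise)
      }
      sample_id <- sprintf("%s_s%02d", co$cohort_id, s)
      rows[[sample_id]] <- val
      ph <- stats::setNames(rep(NA_real_, length(traits)), traits)
      for (tr in traits) {
        mu <- if (!is.null(co$trait_means) && tr %in% names(co$trait_means))
          co$trait_means[[tr]] else 0
        eff <- 0; latv <- 0
        if (!is.null(links)) {
          li <- which(links$phenotype == tr & links$module %in% modules)
          if (length(li)) {
            eff <- links$effect[li[1L]]
            latv <- z[[as.character(links$module[li[1L]])]]
          }
        }
        ph[[tr]] <- mu + trait_sd * (eff * latv + sqrt(max(0, 1 - eff^2)) * stats::rnorm(1))
      }
      pheno[[sample_id]] <- data.frame(sample = sample_id, cohort = co$cohort_id,
                                       t(ph), check.names = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- genes
  phenotypes <- do.call(rbind, pheno)
  rownames(phenotypes) <- NULL
  truth <- list(module_assignments = mod[!is.na(mod)],
                module_trait_links = links,
                exocrine_types = exocrine_types,
                noise_cv = noise_cv,
                contamination_fraction = contamination_fraction)
  structure(list(counts = counts, phenotypes = phenotypes, truth = truth),
            class = "bulk_dataset")
}

#' Simulate normalized bulk expression with planted co-expression modules
#'
#' Direct generator for network-stage validation: standard-normal expression
#' for `n_genes` across `n_samples`, with `n_modules` planted blocks whose
#' genes share a latent factor (pairwise correlation `within_cor`), remaining
#' genes independent noise. The first module is linked to the first phenotype
#' with latent correlation `trait_effect`; remaining phenotypes are noise.
#'
#' @param n_samples,n_genes,n_modules,module_size Dimensions of the design.
#' @param within_cor Pairwise correlation within a planted module.
#' @param trait_effect Correlation between the linked module's latent factor
#'   and the first phenotype (0 disables the link).
#' @param n_traits Number of phenotypes.
#' @param seed Integer seed.
#' @return List: `expr` (samples x genes), `phenotypes` (samples x traits
#'   data.frame), `truth` (`modules` per gene with "none" for noise genes,
#'   `linked_module`, `linked_trait`).
#' @export
simulate_coexpression <- function(n_samples = 32, n_genes = 300, n_modules = 3,
                                  module_size = 20, within_cor = 0.8,
                                  trait_effect = 0.8, n_traits = 3, seed = 1) {
  stopifnot(n_modules * module_size <= n_genes, within_cor >= 0, within_cor <= 1)
  set.seed(as.integer(seed))
  lab <- rep("none", n_genes)
  for (m in seq_len(n_modules))
    lab[((m - 1) * module_size + 1):(m * module_size)] <- paste0("M", m)
  z <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules,
              dimnames = list(NULL, paste0("M", seq_len(n_modules))))
  expr <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  for (j in seq_len(n_genes)) {
    if (lab[j] != "none")
      expr[, j] <- sqrt(within_cor) * z[, lab[j]] +
        sqrt(1 - within_cor) * expr[, j]
  }
  colnames(expr) <- sprintf("gene_%03d", seq_len(n_genes))
  names(lab) <- colnames(expr)
  rownames(expr) <- sprintf("sample_%02d", seq_len(n_samples))
  ph <- matrix(stats::rnorm(n_samples * n_traits), n_samples, n_traits,
               dimnames = list(rownames(expr), paste0("trait_", seq_len(n_traits))))
  if (n_modules >= 1 && trait_effect > 0)
    ph[, 1] <- trait_effect * z[, 1] + sqrt(1 - trait_effect^2) * stats::rnorm(n_samples)
  list(expr = expr,
       phenotypes = data.frame(sample = rownames(expr), ph,
                               check.names = FALSE),
       truth = list(modules = lab,
                    linked_module = if (trait_effect > 0) "M1" else NA_character_,
                    linked_trait = if (trait_effect > 0) "trait_1" else NA_character_))
}

#' Build a six-cohort islet study with planted beta-cell-specific genes
#'
#' Convenience scenario builder: `n_specific` genes concentrate essentially
#' all expected expression in beta cells (high beta mean there, rare and weak
#' detection elsewhere); the remaining genes are expressed comparably in all
#' cell types so that the beta-cell share stays well below the calling
#' threshold. Default cohorts follow the six age x diet x sex groups.
#'
#' @param n_genes Total genes.
#' @param n_specific Number of planted beta-cell-specific genes.
#' @param cell_types Cell types; first entry is the target (beta) type.
#' @param n_cells_per_type Cells per type per cohort.
#' @param cohort_ids Cohort labels.
#' @param seed Integer seed (used for background expression levels).
#' @return List: `specs` ([gene_specs()] table), `cohorts`, `truth`
#'   (with `specific_genes`).
#' @export
simulate_islet_study <- function(n_genes = 50, n_specific = 10,
                                 cell_types = c("beta", "alpha", "delta", "acinar"),
                                 n_cells_per_type = 300,
                                 cohort_ids = c("HF20", "HM20", "HF30", "HM30",
                                                "LF20", "LM20"),
                                 seed = 1) {
  stopifnot(n_specific <= n_genes, length(cell_types) >= 2)
  set.seed(as.integer(seed))
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  specific <- genes[seq_len(n_specific)]
  rows <- list()
  for (g in genes) {
    if (g %in% specific) {
      for (ty in cell_types) {
        if (ty == cell_types[1L])
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, cell_type = ty, alpha = 4, beta_ = 1,
            pi0 = 0.1, pr_dropout = 0.9)
        else
          # rarely detected off-target: few nonzero cells, tiny mean
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, cell_type = ty, alpha = 0.5, beta_ = 19.5,
            pi0 = 0.96, pr_dropout = 0.5)
      }
    } else {
      # background gene: comparable expression everywhere (beta share <= ~0.4)
      base <- stats::runif(1, 1, 3)
      for (ty in cell_types) {
        a <- base * stats::runif(1, 0.8, 1.25)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, cell_type = ty, alpha = a, beta_ = 2 * base,
          pi0 = 0.3, pr_dropout = 0.9)
      }
    }
  }
  specs <- gene_specs(do.call(rbind, rows))
  cohorts <- lapply(cohort_ids, function(id)
    cohort_spec(id, stats::setNames(rep(n_cells_per_type, length(cell_types)),
                                    cell_types)))
  list(specs = specs, cohorts = cohorts,
       truth = list(specific_genes = specific, target = cell_types[1L]))
}

#' Write a synthetic dataset to disk in 10x/TSV formats
#'
#' Writes `matrix.mtx` + `features.tsv` + `barcodes.tsv` (genes x cells, 10x
#' convention, orientation recorded in `layout.json`), the cell metadata TSV,
#' bulk counts (genes as rows, samples as columns) and phenotype TSVs when a
#' bulk dataset is supplied, and the ground truth as JSON. Round-trips
#' losslessly through [read_expression()].
#'
#' @param dataset An `annotated_expression` from [generate_cells()].
#' @param out_dir Output directory (created if needed).
#' @param bulk Optional `bulk_dataset` from [generate_bulk()].
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(dataset, out_dir, bulk = NULL) {
  stopifnot(inherits(dataset, "annotated_expression"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(dataset$matrix), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(out_dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = dataset$gene_ids,
                                gene_name = dataset$gene_ids),
                     file.path(out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dataset$cell_meta$barcode, file.path(out_dir, "barcodes.tsv"))
  utils::write.table(dataset$cell_meta, file.path(out_dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(matrix_orientation = "genes_x_cells"),
                       file.path(out_dir, "layout.json"), auto_unbox = TRUE)
  truth <- dataset$truth
  truth$cohorts <- lapply(truth$cohorts, unclass)
  truth$gene_specs <- as.data.frame(truth$gene_specs)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(bulk)) {
    bt <- t(bulk$counts)  # genes rows, samples columns
    utils::write.table(data.frame(gene_id = rownames(bt), bt, check.names = FALSE),
                       file.path(out_dir, "bulk_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bulk$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
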