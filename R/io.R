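# Readers, writers, and the pipeline orchestrator.

#' Read annotated single-cell expression
#'
#' Accepts either a 10x-style MatrixMarket triplet directory
#' (`matrix.mtx` + `features.tsv` + `barcodes.tsv`, genes x cells unless the
#' sidecar `layout.json` says otherwise) or a dense TSV (genes as rows,
#' cells as columns, first column gene ids). Orientation is normalized to
#' cells x genes internally. Metadata are joined strictly by barcode; any
#' barcode missing from the metadata is an error naming it. Duplicate gene
#' names are disambiguated with `.1`, `.2`, ... suffixes and logged.
#'
#' @param path Directory (MTX triplet) or TSV file.
#' @param meta Optional data.frame with a `barcode` column, or path to the
#'   `cells.tsv` written by [write_fixture()] (read automatically from an
#'   MTX directory when present).
#' @return `annotated_expression` list: `matrix` (cells x genes, dense),
#'   `cell_meta`, `gene_ids`, `truth = NULL`.
#' @export
read_expression <- function(path, meta = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- readLines(bc)
    orientation <- "genes_x_cells"
    side <- file.path(path, "layout.json")
    if (file.exists(side))
      orientation <- jsonlite::read_json(side)$matrix_orientation %||% orientation
    if (orientation == "genes_x_cells") m <- t(m)
    if (ncol(m) != nrow(features))
      stop("dimension mismatch between matrix.mtx (", ncol(m),
           " genes) and features.tsv (", nrow(features), " rows)")
    if (nrow(m) != length(barcodes))
      stop("dimension mismatch between matrix.mtx (", nrow(m),
           " cells) and barcodes.tsv (", length(barcodes), " rows)")
    genes <- as.character(features[[1L]])
    if (is.null(meta) && file.exists(file.path(path, "cells.tsv")))
      meta <- file.path(path, "cells.tsv")
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- t(as.matrix(tab[, -1L, drop = FALSE]))
    barcodes <- rownames(m)
  }
  if (anyDuplicated(genes)) {
    message(sum(duplicated(genes)), " duplicate gene name(s) disambiguated")
    genes <- make.unique(genes)
  }
  dimnames(m) <- list(barcodes, genes)
  cell_meta <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    if (is.character(meta) && length(meta) == 1L)
      meta <- utils::read.table(meta, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    if (!"barcode" %in% names(meta)) stop("metadata must have a 'barcode' column")
    missing <- setdiff(barcodes, meta$barcode)
    if (length(missing))
      stop("metadata missing barcode(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    cell_meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
    rownames(cell_meta) <- NULL
  }
  structure(list(matrix = m, cell_meta = cell_meta, gene_ids = genes,
                 truth = NULL),
            class = "annotated_expression")
}

#' Read a bulk count table
#'
#' TSV with genes as rows (first column gene ids) and samples as columns.
#'
#' @param path TSV path.
#' @return Samples x genes matrix.
#' @export
read_bulk <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(m) <- as.character(tab[[1L]])
  m
}

#' Run the integrated analysis pipeline
#'
#' Executes the stages in order -- qc, hurdle/specific-gene calling,
#' markers, composition, permutation overlap, phenotype pass-through, and
#' the co-expression network -- persisting each stage's outputs as TSV under
#' `out_dir` and a JSON manifest recording the configuration and seeds.
#' Reruns with the same configuration are reproducible. A failing stage
#' halts with an error naming the stage; earlier outputs are preserved.
#'
#' @param sc `annotated_expression` with `cell_type`, `subtype`, `cohort`
#'   metadata (raw counts or unit-interval synthetic expression).
#' @param out_dir Output directory.
#' @param bulk Optional samples x genes bulk count matrix.
#' @param bulk_pheno Optional phenotype data.frame aligned to bulk samples.
#' @param target Target cell type for specific-gene calling.
#' @param stages Character vector of stages to run (subset of
#'   `c("qc", "specific", "markers", "composition", "permutation",
#'   "network")`).
#' @param config List of tunables: `tau`, `dropout_grid_step`, `n_min`,
#'   `power`, `n_boot`, `n_sample`, `n_perm`, `seed`, `already_normalized`
#'   (skip log-normalization, e.g. for synthetic unit-interval data),
#'   `skip_threshold_qc` (synthetic data has no count-scale QC metrics).
#' @return Invisibly, a list of stage results; files under `out_dir`.
#' @export
run_pipeline <- function(sc, out_dir, bulk = NULL, bulk_pheno = NULL,
                         target = "beta",
                         stages = c("qc", "specific", "markers",
                                    "composition", "permutation", "network"),
                         config = list()) {
  stopifnot(inherits(sc, "annotated_expression"))
  defaults <- list(tau = 0.8, dropout_grid_step = 0.01,
                   n_min = 20, power = 8, n_boot = 100,
                   n_sample = 1000, n_perm = 1000, seed = 1,
                   already_normalized = FALSE,
                   skip_threshold_qc = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  wr <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr <- sc$matrix
  meta <- sc$cell_meta
  if ("qc" %in% stages) stage("qc", function() {
    if (!cfg$skip_threshold_qc) {
      tf <- threshold_filter(expr)
      keep1 <- tf$report$pass
    } else keep1 <- rep(TRUE, nrow(expr))
    nc <- rowSums(expr[keep1, , drop = FALSE])
    nf <- rowSums(expr[keep1, , drop = FALSE] > 0)
    keep2 <- residual_filter(nc, nf)
    kept <- which(keep1)[keep2]
    qc_report <- data.frame(barcode = rownames(expr) %||% seq_len(nrow(expr)),
                            pass = seq_len(nrow(expr)) %in% kept)
    wr(qc_report, "qc_report.tsv")
    expr <<- expr[kept, , drop = FALSE]
    meta <<- meta[kept, , drop = FALSE]
    res$qc <<- qc_report
  })
  norm <- if (cfg$already_normalized) expr else log_normalize(expr)

  if ("specific" %in% stages) stage("specific", function() {
    fits <- fit_cell_type_models(norm, meta,
                                 dropout_grid_step = cfg$dropout_grid_step,
                                 n_min = cfg$n_min)
    tabs <- lapply(names(fits$expected), function(co)
      contribution_table(fits$expected[[co]], fits$cell_counts[[co]]))
    names(tabs) <- names(fits$expected)
    calls <- call_specific_genes(tabs, target, tau = cfg$tau)
    wr(fits$fits, "hurdle_fits.tsv")
    wr(calls, "specific_genes.tsv")
    res$specific <<- calls
  })

  if ("markers" %in% stages) stage("markers", function() {
    bmask <- meta$cell_type == target & !is.na(meta$subtype)
    if (sum(bmask) >= 6L && length(unique(meta$subtype[bmask])) >= 2L) {
      prof <- subtype_profiles(norm[bmask, , drop = FALSE], meta$subtype[bmask])
      tab <- do.call(rbind, lapply(names(prof), function(s)
        cbind(subtype = s, prof[[s]]$table)))
      wr(tab, "subtype_markers.tsv")
      res$markers <<- prof
    }
  })

  if ("composition" %in% stages) stage("composition", function() {
    bmask <- meta$cell_type == target & !is.na(meta$subtype)
    if (any(bmask)) {
      est <- bootstrap_proportions(meta$subtype[bmask], meta$cohort[bmask],
                                   n_sample = cfg$n_sample,
                                   n_boot = cfg$n_boot, seed = cfg$seed)
      wr(est, "composition.tsv")
      if (length(unique(est$cohort)) >= 2L)
        wr(compare_compositions(est), "composition_comparisons.tsv")
      res$composition <<- est
    }
  })

  if ("permutation" %in% stages) stage("permutation", function() {
    if (!is.null(res$specific) && !is.null(res$markers)) {
      spec_genes <- res$specific$gene_id[res$specific$called]
      first <- res$markers[[1L]]$markers
      if (length(spec_genes) && length(first)) {
        ot <- overlap_permutation_test(spec_genes, first, sc$gene_ids,
                                       n_perm = cfg$n_perm, seed = cfg$seed)
        wr(data.frame(observed = ot$observed, p_value = ot$p_value,
                      null_mean = mean(ot$null_overlaps),
                      n_perm = ot$n_perm), "overlap_test.tsv")
        res$overlap <<- ot
      }
    }
  })

  if ("network" %in% stages && !is.null(bulk)) stage("network", function() {
    gsel <- if (!is.null(res$specific)) {
      g <- res$specific$gene_id[res$specific$called]
      if (length(g) >= 10L) g else colnames(bulk)
    } else colnames(bulk)
    nb <- normalize_bulk(bulk[, gsel, drop = FALSE])
    z <- inverse_normal_transform(nb)
    adj <- adjacency_matrix(suppressWarnings(bicor(z)), cfg$power)
    tom <- tom_matrix(adj)
    labels <- detect_modules(tom)
    wr(data.frame(gene = names(labels), module = unname(labels)),
       "modules.tsv")
    if (any(labels != "unassigned")) {
      eg <- eigengene(z, labels)
      wr(data.frame(sample = rownames(bulk), eg), "eigengenes.tsv")
      if (!is.null(bulk_pheno)) {
        mt <- module_trait(eg, bulk_pheno)
        wr(mt, "module_trait.tsv")
        res$module_trait <<- mt
      }
      wr(k_within(adj, labels), "k_within.tsv")
      wr(edge_list(adj, min_weight = 0.01), "edges.tsv")
    }
    res$modules <<- labels
  })

  manifest <- list(package_version = as.character(utils::packageVersion("isletdecon")),
                   config = cfg, stages = stages, target = target,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
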