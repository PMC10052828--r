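# Derivation of islet functional phenotypes from raw assay measurements.

#' Islet secretion/content assay
#'
#' Holds duplicate measurements from a static glucose-stimulated insulin
#' secretion assay: insulin secreted at 2.8 mM and 11 mM glucose, insulin in
#' the content tubes, and total islet protein, together with the assay
#' dilution factors (secretion tubes 1:5, content tubes 1:100 by default).
#' Duplicates are averaged before any ratio is taken.
#'
#' @param secretion_low,secretion_high Insulin at 2.8 / 11 mM glucose
#'   (duplicate pairs, or single values).
#' @param content_insulin Insulin in the content tubes (duplicate pair).
#' @param total_protein Total islet protein (duplicate pair).
#' @param dilution_secretion,dilution_content Dilution multipliers applied to
#'   secretion and content measurements (set to 1 when the inputs are already
#'   dilution-corrected).
#' @return Object of class `islet_assay`.
#' @export
islet_assay <- function(secretion_low, secretion_high, content_insulin,
                        total_protein, dilution_secretion = 5,
                        dilution_content = 100) {
  vals <- c(secretion_low, secretion_high, content_insulin, total_protein)
  if (any(vals < 0)) stop("assay measurements must be non-negative")
  structure(list(secretion_low = secretion_low,
                 secretion_high = secretion_high,
                 content_insulin = content_insulin,
                 total_protein = total_protein,
                 dilution_secretion = dilution_secretion,
                 dilution_content = dilution_content),
            class = "islet_assay")
}

#' Derive islet functional phenotypes
#'
#' Averages duplicates, applies the dilution multipliers, and computes:
#' glucose-stimulated insulin secretion `gsis = secretion_high /
#' secretion_low` (same-dilution ratio, so the secretion dilution cancels and
#' is applied once, never doubly); `insulin_content = content_insulin /
#' total_protein` (insulin per unit protein); `basal_secretion =
#' secretion_low / insulin_content`. Zero denominators yield `NA` with an
#' `undefined` flag rather than being dropped.
#'
#' @param assay An [islet_assay()].
#' @return data.frame with `phenotype`, `value`, `units`, `undefined`.
#' @export
derive_phenotypes <- function(assay) {
  stopifnot(inherits(assay, "islet_assay"))
  s_low <- mean(assay$secretion_low) * assay$dilution_secretion
  s_high <- mean(assay$secretion_high) * assay$dilution_secretion
  content <- mean(assay$content_insulin) * assay$dilution_content /
    ifelse(mean(assay$total_protein) > 0, mean(assay$total_protein), NA_real_)
  gsis <- if (s_low > 0) s_high / s_low else NA_real_
  basal <- if (!is.na(content) && content > 0) s_low / content else NA_real_
  data.frame(
    phenotype = c("gsis", "basal_secretion", "insulin_content"),
    value = c(gsis, basal, content),
    units = c("ratio (11 mM / 2.8 mM secretion)",
              "secreted insulin / insulin content",
              "insulin per unit total protein"),
    undefined = c(is.na(gsis), is.na(basal), is.na(content)),
    row.names = NULL)
}
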