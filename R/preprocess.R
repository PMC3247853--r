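#' Full pre-processing pipeline
#'
#' Runs the fixed pre-processing order used before variance-component
#' modelling: probabilistic quotient normalization (reference spectrum from
#' study aliquots only), removal of reference wells and of multivariate
#' outlier aliquots, then a per-antibody Box-Cox transformation. Replicate
#' concordance is computed on the raw and on the normalized table so the
#' effect of normalization on technical reproducibility can be reported.
#'
#' @param raw A raw-stage [intensity_table()] consistent with `design`
#'   (study aliquots, optionally plus reference wells).
#' @param design The [generate_design()] result the table was measured on.
#' @param alpha Outlier tail probability passed to [detect_outliers()].
#' @return A list with `transformed` (transformed-stage table, outliers and
#'   reference wells dropped), `outliers` (the [detect_outliers()] report),
#'   `concordance_before`, `concordance_after` (see
#'   [replicate_concordance()]; `NULL` when the design has fewer than 3
#'   duplicate pairs), and `boxcox` (per-antibody `lambda`).
#' @export
preprocess_pipeline <- function(raw, design, alpha = 1e-4) {
  stopifnot(inherits(raw, "intensity_table"),
            inherits(design, "cohort_design"))
  study_ids <- intersect(design$aliquots$aliquot_id, rownames(raw$values))
  if (length(study_ids) < nrow(design$aliquots))
    stop("raw table is missing ",
         nrow(design$aliquots) - length(study_ids), " design aliquots")

  map <- duplicate_map(design)
  conc <- function(tab) {
    if (nrow(map) >= 3) replicate_concordance(tab, map) else NULL
  }
  conc_before <- conc(raw)

  normalized <- pqn_normalize(raw, reference_rows = study_ids)
  conc_after <- conc(normalized)

  study <- intensity_table(
    normalized$values[study_ids, , drop = FALSE], "normalized")
  report <- detect_outliers(study, alpha)
  keep <- setdiff(study_ids, report$flagged)

  kept <- study$values[keep, , drop = FALSE]
  lambdas <- numeric(ncol(kept))
  transformed <- kept
  for (k in seq_len(ncol(kept))) {
    fit <- boxcox_fit_transform(kept[, k])
    lambdas[k] <- fit$lambda
    transformed[, k] <- fit$transformed
  }
  names(lambdas) <- colnames(kept)

  list(transformed = intensity_table(transformed, "transformed"),
       outliers = report,
       concordance_before = conc_before,
       concordance_after = conc_after,
       boxcox = lambdas)
}
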