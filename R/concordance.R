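#' Duplicate-aliquot map of a design
#'
#' Pairs of aliquot IDs measuring the same serum sample (replicates 1 and 2).
#'
#' @param design A [generate_design()] result.
#' @return Data frame with columns `sample_id`, `aliquot_1`, `aliquot_2`.
#' @export
duplicate_map <- function(design) {
  a <- design$aliquots
  r1 <- a[a$replicate == 1L, ]
  r2 <- a[a$replicate == 2L, ]
  data.frame(
    sample_id = r2$sample_id,
    aliquot_1 = r1$aliquot_id[match(r2$sample_id, r1$sample_id)],
    aliquot_2 = r2$aliquot_id,
    stringsAsFactors = FALSE
  )
}

#' Replicate concordance by antibody
#'
#' Quantifies technical reproducibility as, for each antibody, the Spearman
#' rank correlation between first- and second-aliquot intensities across
#' duplicated samples. Ties receive average ranks. An antibody whose
#' replicate vector is constant has undefined correlation and is reported as
#' `NA` and excluded from the cohort median and IQR.
#'
#' @param table An [intensity_table()] at any stage.
#' @param map A duplicate map as returned by [duplicate_map()]: one row per
#'   duplicated sample with columns `aliquot_1`, `aliquot_2`.
#' @return An object of class `concordance_result`: list with `r` (named
#'   per-antibody correlations), `median`, `iqr` (length-2, linear
#'   interpolation between order statistics), and `map`.
#' @export
replicate_concordance <- function(table, map) {
  stopifnot(inherits(table, "intensity_table"),
            all(c("aliquot_1", "aliquot_2") %in% names(map)))
  x <- table$values
  present <- map$aliquot_1 %in% rownames(x) & map$aliquot_2 %in% rownames(x)
  map <- map[present, , drop = FALSE]
  if (nrow(map) < 3)
    stop("replicate concordance needs at least 3 complete duplicate pairs, ",
         "got ", nrow(map))
  v1 <- x[map$aliquot_1, , drop = FALSE]
  v2 <- x[map$aliquot_2, , drop = FALSE]
  r <- vapply(seq_len(ncol(x)), function(k) {
    if (stats::sd(v1[, k]) == 0 || stats::sd(v2[, k]) == 0) return(NA_real_)
    stats::cor(v1[, k], v2[, k], method = "spearman")
  }, numeric(1))
  names(r) <- colnames(x)
  ok <- r[!is.na(r)]
  structure(list(r = r,
                 median = if (length(ok)) stats::median(ok) else NA_real_,
                 iqr = if (length(ok))
                   stats::quantile(ok, c(0.25, 0.75), names = FALSE)
                 else c(NA_real_, NA_real_),
                 map = map),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Replicate concordance over", nrow(x$map), "duplicate pairs:",
      "median Spearman r =", round(x$median, 3),
      sprintf("(IQR %.3f-%.3f)\n", x$iqr[1], x$iqr[2]))
  invisible(x)
}
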