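#' Cohort-level summary of variance-proportion breakdowns
#'
#' Medians and interquartile ranges, across antibodies, of the percentages
#' of total phenotypic variance (fam, env, cv, iv, exp, and their stable
#' combination fam + env computed per antibody before summarising) and of
#' non-experimental variance (fam_ne, env_ne, stable_ne, cv_ne, iv_ne).
#' Antibodies whose non-experimental proportions are undefined (all variance
#' experimental) are excluded from the non-experimental summaries only; the
#' count `n` entering each summary is reported alongside.
#'
#' @param breakdowns A list of [variance_proportions()] results, or a data
#'   frame with columns `fam`, `env`, `cv`, `iv`, `exp` (and optionally the
#'   `_ne` columns).
#' @return A data frame with columns `component`, `median`, `q1`, `q3`, `n`.
#'   Quartiles use linear interpolation between order statistics.
#' @export
cohort_summary <- function(breakdowns) {
  if (is.data.frame(breakdowns)) {
    df <- breakdowns
  } else {
    if (length(breakdowns) == 0) stop("empty list of breakdowns")
    stopifnot(all(vapply(breakdowns, inherits, TRUE, "proportion_breakdown")))
    df <- do.call(rbind, lapply(breakdowns, function(b)
      as.data.frame(unclass(b))))
  }
  if (nrow(df) == 0) stop("empty list of breakdowns")
  need <- c("fam", "env", "cv", "iv", "exp")
  stopifnot(all(need %in% names(df)))
  df$stable <- df$fam + df$env
  if (all(c("fam_ne", "env_ne") %in% names(df)))
    df$stable_ne <- df$fam_ne + df$env_ne
  comps <- intersect(c("fam", "env", "cv", "iv", "exp", "stable",
                       "fam_ne", "env_ne", "stable_ne", "cv_ne", "iv_ne"),
                     names(df))
  out <- lapply(comps, function(cc) {
    x <- df[[cc]]
    x <- x[!is.na(x)]
    data.frame(component = cc,
               median = if (length(x)) stats::median(x) else NA_real_,
               q1 = if (length(x)) stats::quantile(x, 0.25, names = FALSE)
                    else NA_real_,
               q3 = if (length(x)) stats::quantile(x, 0.75, names = FALSE)
                    else NA_real_,
               n = length(x))
  })
  do.call(rbind, out)
}

#' Published reference variance decomposition of 66 serum antibodies
#'
#' The per-antibody percentages of total phenotypic variance (familial,
#' individual environment, common visit, individual visit, experimental)
#' reported for 66 Human Protein Atlas antibodies in a longitudinal twin
#' serum study, as printed. Used as a worked reference for the summary
#' statistics (medians 12% familial, 63% experimental, 0% common visit).
#'
#' @return Data frame with columns `antibody_id`, `gene`, `fam`, `env`,
#'   `cv`, `iv`, `exp` (66 rows).
#' @export
reference_variance_table <- function() {
  path <- system.file("extdata", "hpa_variance_reference.csv",
                      package = "twinvar", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# round half away from zero (integer comparisons against published medians)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
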