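#' Random-effect grouping labels for the twin model
#'
#' Maps every aliquot to the group label of each random effect: H at the
#' twin-pair level; M at the pair level for MZ aliquots and the individual
#' level for DZ aliquots (the structure that yields co-twin covariance
#' `var_H + var_M + var_W` for MZ and `var_H + var_W` for DZ pairs); E at the
#' individual level; W per pair-visit; V per individual-visit. Duplicate
#' aliquots of one sample share all five labels, so only the residual
#' separates them.
#'
#' @param design A [generate_design()] result.
#' @param aliquot_ids Optional subset of aliquot IDs (e.g. after outlier
#'   removal); defaults to all study aliquots.
#' @return An object of class `random_effect_groups`: a data frame with row
#'   names = aliquot IDs and columns `pair`, `H`, `M`, `E`, `W`, `V`,
#'   `plate`, `well`, `zygosity`.
#' @export
build_grouping <- function(design, aliquot_ids = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  a <- design$aliquots
  if (!is.null(aliquot_ids)) {
    missing_ids <- setdiff(aliquot_ids, a$aliquot_id)
    if (length(missing_ids)) stop("unknown aliquot IDs: ",
                                  paste(missing_ids, collapse = ", "))
    a <- a[match(aliquot_ids, a$aliquot_id), ]
  }
  zyg <- unique(a$zygosity)
  if (length(zyg) < 2)
    stop("design contains only ", zyg, " pairs: the familial split into H ",
         "and M is not identifiable; request a combined familial variance ",
         "on a design with both zygosities")
  g <- data.frame(
    pair = a$pair_id,
    H = a$pair_id,
    M = ifelse(a$zygosity == "MZ", a$pair_id, a$individual_id),
    E = a$individual_id,
    W = paste(a$pair_id, a$visit, sep = ":"),
    V = paste(a$individual_id, a$visit, sep = ":"),
    plate = a$plate,
    well = a$well,
    zygosity = a$zygosity,
    row.names = a$aliquot_id,
    stringsAsFactors = FALSE
  )
  class(g) <- c("random_effect_groups", "data.frame")
  g
}

#' Marginal covariance implied by the twin model
#'
#' The covariance of the aliquot vector under the model is block-diagonal
#' with one block per twin pair (no random effect spans pairs). Each block is
#' `var_eps * I` plus, for each random effect, its variance times the
#' indicator of the two aliquots sharing that effect's group.
#'
#' @param groups A [build_grouping()] result.
#' @param components A [variance_components()] object (all entries >= 0).
#' @param dense If `TRUE`, return one dense matrix in the row order of
#'   `groups`; otherwise a named list with one block per pair.
#' @return A list of per-pair covariance blocks (dimnames = aliquot IDs), or
#'   a single dense matrix.
#' @export
marginal_covariance <- function(groups, components, dense = FALSE) {
  stopifnot(inherits(groups, "random_effect_groups"),
            inherits(components, "variance_components"))
  eff <- c(H = "var_H", M = "var_M", E = "var_E", W = "var_W", V = "var_V")
  blocks <- lapply(split(seq_len(nrow(groups)), groups$pair), function(idx) {
    m <- length(idx)
    S <- diag(components[["var_eps"]], m)
    for (e in names(eff)) {
      lab <- groups[[e]][idx]
      S <- S + components[[eff[e]]] * outer(lab, lab, "==")
    }
    dimnames(S) <- list(rownames(groups)[idx], rownames(groups)[idx])
    S
  })
  if (!dense) return(blocks)
  n <- nrow(groups)
  out <- matrix(0, n, n, dimnames = list(rownames(groups), rownames(groups)))
  for (S in blocks) out[rownames(S), colnames(S)] <- S
  out
}
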