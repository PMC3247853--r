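#' Probabilistic quotient normalization
#'
#' Removes per-aliquot multiplicative dilution from a raw intensity table.
#' The reference spectrum is the antibody-wise median across the reference
#' rows (by default all rows); each aliquot is divided by the median of its
#' per-antibody quotients against that reference.
#'
#' @param table A raw-stage [intensity_table()].
#' @param reference_policy Reference spectrum choice; only
#'   `"median_spectrum"` is implemented.
#' @param reference_rows Optional character vector of aliquot IDs over which
#'   the reference spectrum is computed (e.g. study aliquots only, excluding
#'   reference wells). All rows are normalized regardless.
#' @param allow_single Allow a single-antibody table (the median quotient is
#'   then the single quotient, i.e. plain reference scaling)? Default FALSE.
#' @return A normalized-stage [intensity_table()] of the same shape.
#' @examples
#' m <- matrix(c(2, 4, 6, 1, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a1", "a2"), c("k1", "k2", "k3")))
#' pqn_normalize(intensity_table(m, "raw"))
#' @export
pqn_normalize <- function(table, reference_policy = "median_spectrum",
                          reference_rows = NULL, allow_single = FALSE) {
  stopifnot(inherits(table, "intensity_table"))
  reference_policy <- match.arg(reference_policy)
  if (table$stage != "raw")
    stop("pqn_normalize expects a raw-stage table, got ", table$stage)
  x <- table$values
  if (nrow(x) < 2) stop("PQN requires at least 2 aliquots")
  if (ncol(x) < 2 && !allow_single)
    stop("single-antibody table: the median quotient is degenerate ",
         "(set allow_single = TRUE to scale by the reference anyway)")
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive intensity at aliquot ", rownames(x)[bad[1]],
         ", antibody ", colnames(x)[bad[2]])
  }
  ref_x <- if (is.null(reference_rows)) x else {
    missing_ids <- setdiff(reference_rows, rownames(x))
    if (length(missing_ids)) stop("unknown reference rows: ",
                                  paste(missing_ids, collapse = ", "))
    x[reference_rows, , drop = FALSE]
  }
  reference <- apply(ref_x, 2, stats::median)
  quotients <- sweep(x, 2, reference, "/")
  factors <- apply(quotients, 1, stats::median)
  out <- x / factors
  res <- intensity_table(out, "normalized")
  attr(res, "reference_spectrum") <- reference
  attr(res, "dilution_factors") <- factors
  res
}
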