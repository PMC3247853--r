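#' Upper-tail chi-squared cutoff
#'
#' Upper-`alpha` quantile of the chi-squared distribution, used as the
#' threshold for squared Mahalanobis distances of bivariate principal
#' component scores (`chi2_cutoff(2, 1e-4)` is 18.42 to two decimals; for
#' 2 degrees of freedom the closed form is `-2 * log(alpha)`).
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The threshold value.
#' @export
chi2_cutoff <- function(df, alpha) {
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Multivariate outlier screen on principal-component scores
#'
#' Standardizes each antibody column to mean 0 and SD 1, projects the
#' aliquots onto the first two right-singular directions of the standardized
#' matrix, and computes each aliquot's squared Mahalanobis distance from the
#' origin under the empirical diagonal covariance of the two score vectors
#' (scores of distinct singular directions are exactly orthogonal). Aliquots
#' whose distance exceeds `chi2_cutoff(2, alpha)` are flagged.
#'
#' @param table A normalized-stage [intensity_table()].
#' @param alpha Upper-tail probability of the chi-squared(2) reference
#'   distribution (default 1e-4, threshold 18.42).
#' @return An object of class `outlier_report`: list with `distance` (named
#'   squared distances), `threshold`, `flagged` (aliquot IDs), and `scores`
#'   (n x 2 matrix of the two projection coordinates).
#' @export
detect_outliers <- function(table, alpha = 1e-4) {
  stopifnot(inherits(table, "intensity_table"))
  x <- table$values
  if (nrow(x) < 3) stop("outlier detection needs at least 3 aliquots")
  if (ncol(x) < 2) stop("outlier detection needs at least 2 antibodies")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant antibody column: ", colnames(x)[which(sds == 0)[1]])
  z <- scale(x)
  sv <- svd(z, nu = 2, nv = 2)
  if (sum(sv$d > max(dim(z)) * .Machine$double.eps * sv$d[1]) < 2)
    stop("standardized matrix has rank < 2")
  scores <- sv$u %*% diag(sv$d[1:2], 2)
  rownames(scores) <- rownames(x)
  colnames(scores) <- c("pc1", "pc2")
  v <- apply(scores, 2, stats::var)
  d2 <- scores[, 1]^2 / v[1] + scores[, 2]^2 / v[2]
  thr <- chi2_cutoff(2, alpha)
  structure(list(distance = d2, threshold = thr,
                 flagged = rownames(x)[d2 > thr], scores = scores),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier screen:", length(x$flagged), "of", length(x$distance),
      "aliquots above squared-distance threshold",
      round(x$threshold, 2), "\n")
  if (length(x$flagged)) cat(" flagged:", paste(x$flagged, collapse = ", "),
                             "\n")
  invisible(x)
}
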