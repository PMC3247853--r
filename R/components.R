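#' Variance components of the twin mixed-effects model
#'
#' The model decomposes each antibody's transformed intensity into additive,
#' independent Gaussian random effects: a pair-level familial effect H, a
#' zygosity-dependent familial effect M (shared by MZ co-twins, individual
#' for DZ twins), an individual-environment effect E, a common-visit effect W
#' (shared by co-twins sampled the same day), an individual-visit effect V,
#' and a residual experimental effect distinguishing duplicate aliquots.
#' The classical additive-genetic (A), dominance (D) and common-environment
#' (C) variances are not separately identifiable from MZ/DZ covariances
#' alone; H and M re-parameterise them via
#' `Var(H) = A/2 + D/4 + C` and `Var(M) = A/2 + 3D/4`, so that the MZ co-twin
#' covariance is `Var(H) + Var(M) + Var(W)` and the DZ co-twin covariance is
#' `Var(H) + Var(W)`. Familial variance is reported as `Var(H) + Var(M)`.
#'
#' @param var_H,var_M,var_E,var_W,var_V,var_eps Non-negative variances on
#'   the transformed-intensity scale.
#' @param var_A,var_D,var_C Optional generator-only variances; when supplied
#'   they define `var_H` and `var_M` (which must then be omitted).
#' @return A named numeric vector of class `variance_components` with
#'   elements `var_H`, `var_M`, `var_E`, `var_W`, `var_V`, `var_eps`. When
#'   built from A/D/C those are kept as an attribute `acd`.
#' @examples
#' variance_components(var_A = 0.2, var_D = 0.1, var_C = 0.05,
#'                     var_E = 0.1, var_eps = 0.5)
#' @export
variance_components <- function(var_H = 0, var_M = 0, var_E = 0, var_W = 0,
                                var_V = 0, var_eps = 0,
                                var_A = NULL, var_D = NULL, var_C = NULL) {
  acd <- NULL
  if (!is.null(var_A) || !is.null(var_D) || !is.null(var_C)) {
    if (!missing(var_H) || !missing(var_M))
      stop("supply either var_H/var_M or var_A/var_D/var_C, not both")
    var_A <- var_A %||% 0; var_D <- var_D %||% 0; var_C <- var_C %||% 0
    if (min(var_A, var_D, var_C) < 0) stop("variances must be >= 0")
    var_H <- var_A / 2 + var_D / 4 + var_C
    var_M <- var_A / 2 + 3 * var_D / 4
    acd <- c(var_A = var_A, var_D = var_D, var_C = var_C)
  }
  x <- c(var_H = var_H, var_M = var_M, var_E = var_E, var_W = var_W,
         var_V = var_V, var_eps = var_eps)
  if (any(!is.finite(x)) || any(x < 0)) stop("variances must be finite and >= 0")
  structure(x, acd = acd, class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generator specification for one antibody
#'
#' Bundles everything the intensity simulator needs for one antibody: the
#' variance components on the latent (transformed) scale, per-plate mean
#' intensities, optional per-plate linear well-position drift slopes, the
#' Box-Cox exponent lambda whose inverse maps latent values to the raw
#' fluorescence scale, and the standard deviation of the per-aliquot
#' log-normal dilution factor (shared across antibodies of an aliquot).
#'
#' @param antibody_id Character label.
#' @param components A [variance_components()] object.
#' @param plate_means Numeric vector, one mean per plate (recycled if
#'   length 1).
#' @param drift_slopes Per-plate slope on the centered well index
#'   (default 0, i.e. no drift; recycled if length 1).
#' @param boxcox_lambda Box-Cox exponent of the raw scale (default 0:
#'   log-normal raw intensities, typical of fluorescence data).
#' @param dilution_sd SD of `log` dilution factor (default 0).
#' @return An object of class `antibody_spec`.
#' @export
antibody_spec <- function(antibody_id, components, plate_means,
                          drift_slopes = 0, boxcox_lambda = 0,
                          dilution_sd = 0) {
  stopifnot(inherits(components, "variance_components"),
            is.numeric(plate_means), length(plate_means) >= 1,
            dilution_sd >= 0, is.finite(boxcox_lambda))
  structure(list(antibody_id = as.character(antibody_id),
                 components = components,
                 plate_means = plate_means, drift_slopes = drift_slopes,
                 boxcox_lambda = boxcox_lambda, dilution_sd = dilution_sd),
            class = "antibody_spec")
}

#' Box-Cox power transformation and its inverse
#'
#' `boxcox_transform` computes `(y^lambda - 1)/lambda` for `lambda != 0` and
#' `log(y)` for `lambda == 0`; `boxcox_inverse` maps back. The inverse is
#' defined only where `lambda * z + 1 > 0` (always, for `lambda == 0`).
#'
#' @param y Positive values to transform.
#' @param z Transformed values to invert.
#' @param lambda Box-Cox exponent.
#' @return Numeric vector of the same length.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox transform requires strictly positive values")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
boxcox_inverse <- function(z, lambda) {
  if (lambda == 0) return(exp(z))
  arg <- lambda * z + 1
  if (any(arg <= 0))
    stop("inverse Box-Cox undefined: lambda * z + 1 <= 0")
  arg^(1 / lambda)
}
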