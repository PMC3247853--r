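#' Box-Cox transformation by profile maximum likelihood
#'
#' Chooses the Box-Cox exponent that makes one antibody's intensity
#' distribution most nearly Gaussian. For data `y` the profile log-likelihood
#' of lambda (fixed effects reduced to a single mean) is
#' `-n/2 * log(sigma2_hat(lambda)) + (lambda - 1) * sum(log y)`, where
#' `sigma2_hat` is the ML variance of the transformed values. The maximum is
#' located on a closed interval by golden-section search
#' ([stats::optimize()]) to tolerance 1e-6. The fitted transformation is
#' strictly increasing in the input.
#'
#' @param column Strictly positive intensity vector, length >= 10.
#' @param interval Search interval for lambda (default `c(-2, 2)`).
#' @return An object of class `boxcox_fit`: list with `lambda`, `loglik`
#'   (profile log-likelihood at the optimum), and `transformed` (the
#'   Box-Cox–transformed column).
#' @export
boxcox_fit_transform <- function(column, interval = c(-2, 2)) {
  if (length(column) < 10) stop("Box-Cox fit needs at least 10 values")
  if (any(column <= 0)) stop("Box-Cox fit requires strictly positive values")
  if (stats::sd(column) == 0) stop("constant column: Box-Cox fit degenerate")
  ll <- function(lambda) boxcox_loglik(column, lambda)
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE,
                         tol = 1e-6)
  structure(list(lambda = opt$maximum, loglik = opt$objective,
                 transformed = boxcox_transform(column, opt$maximum)),
            class = "boxcox_fit")
}

#' @rdname boxcox_fit_transform
#' @param lambda Exponent at which to evaluate the profile log-likelihood.
#' @export
boxcox_loglik <- function(column, lambda) {
  n <- length(column)
  z <- boxcox_transform(column, lambda)
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(column))
}
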