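#' Fit the twin variance-component model by maximum likelihood
#'
#' Maximizes the Gaussian log-likelihood of one antibody's transformed
#' intensities over the plate fixed effects and the six non-negative variance
#' components (H, M, E, W, V, residual), with the fixed effects profiled out
#' by generalized least squares at every variance iterate and the likelihood
#' evaluated blockwise per twin pair. Model form 1 fits one mean per plate;
#' form 2 adds a plate-specific linear term in the centered well index
#' (intensity drift across the plate). Optimization runs on the
#' standard-deviation scale (lower bound 0, so boundary estimates are
#' reachable) with `L-BFGS-B` from five deterministic starting points spread
#' over dispersed splits of the empirical residual variance; the best
#' converged solution is returned. The response is standardized internally
#' and estimates mapped back, making the fit exactly scale-equivariant.
#'
#' @param y Named numeric vector of transformed intensities; names are
#'   aliquot IDs present in `design` (aliquots dropped during
#'   pre-processing are simply absent — the likelihood uses observed
#'   entries only).
#' @param design The [generate_design()] result.
#' @param model_form 1 (plate means) or 2 (plate means + well drift).
#' @return An object of class `fit_result`: list with `model_form`,
#'   `plate_means`, `drift_slopes` (model 2 only), `components` (a
#'   [variance_components()]), `loglik`, `k` (parameter count:
#'   plates + 6 for model 1, 2*plates + 6 for model 2), `aic` (= 2k - 2
#'   loglik), `converged`, `boundary_eps` (TRUE when the residual variance
#'   hits zero although duplicate aliquots are present), `n`, `n_plates`.
#' @export
fit_variance_model <- function(y, design, model_form = 1) {
  stopifnot(model_form %in% c(1, 2))
  if (is.null(names(y))) stop("y must be named by aliquot ID")
  groups <- build_grouping(design, names(y))
  n <- length(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("y is constant or contains non-finite values")
  mu_y <- mean(y)
  ys <- (as.vector(y) - mu_y) / s  # centering+scaling make the fit exactly
                                   # equivariant under y -> a*y + b

  X <- fixed_design_matrix(groups, model_form)
  bp <- build_block_patterns(groups, X, ys)

  # residual variance of the plate-means OLS fit anchors the start points
  v0 <- mean(stats::lm.fit(X, ys)$residuals^2)
  start_props <- rbind(
    rep(1 / 6, 6),
    c(.04, .04, .04, .04, .04, .80),
    c(.50, .10, .10, .10, .10, .10),
    c(.10, .10, .50, .10, .10, .10),
    c(.20, .20, .10, .10, .20, .20)
  )
  negll <- function(th) -profile_loglik(bp, th^2)$loglik

  best <- NULL
  diags <- character(0)
  for (i in seq_len(nrow(start_props))) {
    th0 <- sqrt(start_props[i, ] * v0)
    res <- tryCatch(
      stats::optim(th0, negll, method = "L-BFGS-B",
                   lower = rep(0, 6), upper = rep(10 * sqrt(v0) + 1, 6),
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diags <- c(diags, sprintf("start %d: %s", i, conditionMessage(res)))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("variance-model optimization failed from every start:\n",
         paste(diags, collapse = "\n"))

  sol <- profile_loglik(bp, best$par^2)
  vars <- best$par^2 * s^2
  loglik <- sol$loglik - n * log(s)
  beta <- sol$beta * s
  n_plates <- length(unique(groups$plate))
  beta[seq_len(n_plates)] <- beta[seq_len(n_plates)] + mu_y
  k <- if (model_form == 1) n_plates + 6 else 2 * n_plates + 6

  comp <- variance_components(var_H = vars[1], var_M = vars[2],
                              var_E = vars[3], var_W = vars[4],
                              var_V = vars[5], var_eps = vars[6])
  has_dups <- anyDuplicated(design$aliquots$sample_id[
    design$aliquots$aliquot_id %in% names(y)]) > 0
  structure(list(
    model_form = model_form,
    plate_means = beta[seq_len(n_plates)],
    drift_slopes = if (model_form == 2) beta[n_plates + seq_len(n_plates)],
    components = comp,
    loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
    converged = best$convergence == 0,
    boundary_eps = has_dups && vars[6] < 1e-10 * sum(vars),
    n = n, n_plates = n_plates
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Twin variance-component fit (model", x$model_form, "): n =", x$n,
      ", lnL =", round(x$loglik, 2), ", AIC =", round(x$aic, 2), "\n")
  print(round(unclass(x$components), 5))
  invisible(x)
}

#' Select between the plate-means and well-drift model forms by AIC
#'
#' Fits both model forms and returns the one with the smaller
#' `AIC = 2k - 2 ln L`; ties go to the simpler model 1. Both candidate AICs
#' are attached to the result.
#'
#' @inheritParams fit_variance_model
#' @return The winning [fit_variance_model()] result with extra fields
#'   `aic_model1` and `aic_model2`.
#' @export
select_model <- function(y, design) {
  f1 <- fit_variance_model(y, design, model_form = 1)
  f2 <- fit_variance_model(y, design, model_form = 2)
  win <- if (f2$aic < f1$aic) f2 else f1
  win$aic_model1 <- f1$aic
  win$aic_model2 <- f2$aic
  win
}
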