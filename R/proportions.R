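#' Variance-proportion breakdown of a fit
#'
#' Converts estimated variance components into the percentages of total
#' phenotypic variance attributable to familiality (`var_H + var_M`),
#' individual environment (E), common visit (W), individual visit (V) and
#' experimental sources (residual), plus the corresponding shares of the
#' non-experimental (biological) variance.
#'
#' @param fit A [fit_variance_model()] result or a [variance_components()]
#'   object.
#' @return An object of class `proportion_breakdown`: list with `fam`,
#'   `env`, `cv`, `iv`, `exp` (percentages summing to 100) and `fam_ne`,
#'   `env_ne`, `cv_ne`, `iv_ne` (percentages of non-experimental variance;
#'   all `NA` when the non-experimental variance is 0).
#' @examples
#' vc <- variance_components(var_H = 0.2, var_M = 0.113, var_E = 0.007,
#'                           var_V = 0.18, var_eps = 0.499)
#' variance_proportions(vc)  # fam 31.3, env 0.7, cv 0, iv 18, exp 49.9
#' @export
variance_proportions <- function(fit) {
  vc <- if (inherits(fit, "fit_result")) fit$components else fit
  stopifnot(inherits(vc, "variance_components"))
  total <- sum(vc)
  if (total == 0) stop("all variance components are zero")
  fam_var <- vc[["var_H"]] + vc[["var_M"]]
  p <- 100 * c(fam = fam_var, env = vc[["var_E"]], cv = vc[["var_W"]],
               iv = vc[["var_V"]], exp = vc[["var_eps"]]) / total
  ne <- total - vc[["var_eps"]]
  pn <- if (ne > 0) {
    100 * c(fam_ne = fam_var, env_ne = vc[["var_E"]], cv_ne = vc[["var_W"]],
            iv_ne = vc[["var_V"]]) / ne
  } else {
    c(fam_ne = NA_real_, env_ne = NA_real_, cv_ne = NA_real_,
      iv_ne = NA_real_)
  }
  structure(as.list(c(p, pn)), class = "proportion_breakdown")
}

#' @export
print.proportion_breakdown <- function(x, ...) {
  cat(sprintf("fam %.1f | env %.1f | cv %.1f | iv %.1f | exp %.1f (%% of total)\n",
              x$fam, x$env, x$cv, x$iv, x$exp))
  if (!is.na(x$fam_ne))
    cat(sprintf("fam %.1f | env %.1f | cv %.1f | iv %.1f (%% of non-experimental)\n",
                x$fam_ne, x$env_ne, x$cv_ne, x$iv_ne))
  invisible(x)
}
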