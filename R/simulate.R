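#' Intensity tables
#'
#' A thin container for an aliquot-by-antibody matrix of fluorescence
#' intensities, tagged with its processing stage. Stages advance only in the
#' order raw -> normalized -> transformed; raw and normalized values must be
#' strictly positive.
#'
#' @param values Numeric matrix, rows named by aliquot ID, columns by
#'   antibody ID.
#' @param stage One of `"raw"`, `"normalized"`, `"transformed"`.
#' @return An object of class `intensity_table` with elements `values` and
#'   `stage`.
#' @export
intensity_table <- function(values, stage = c("raw", "normalized",
                                              "transformed")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix must have aliquot row names and antibody column names")
  if (anyDuplicated(rownames(values))) stop("duplicated aliquot IDs")
  if (stage != "transformed" && any(values <= 0))
    stop(stage, "-stage intensities must be strictly positive")
  structure(list(values = values, stage = stage), class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("Intensity table [", x$stage, "]: ", nrow(x$values), " aliquots x ",
      ncol(x$values), " antibodies\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.intensity_table <- function(x, ...) x$values

# well index centered to mean 0 within each plate over the given wells
centered_well <- function(plate, well) well - stats::ave(well, plate)

#' Simulate raw antibody-array intensities on a cohort design
#'
#' Draws, for each antibody, the additive Gaussian random effects of the twin
#' model — H per pair, M per pair (MZ) or per individual (DZ), E per
#' individual, W per pair-visit, V per individual-visit, and a residual per
#' aliquot — adds the plate mean and any plate-specific linear well-position
#' drift, maps the latent value to the raw fluorescence scale through the
#' inverse Box-Cox transformation at the spec's lambda, and finally applies a
#' per-aliquot multiplicative dilution factor. One standard-normal dilution
#' draw is made per aliquot and scaled by each spec's `dilution_sd`, so with
#' a common `dilution_sd` the factor is identical across all antibodies of an
#' aliquot — the structure probabilistic quotient normalization removes.
#' Reference wells carry a fixed noise-free reference profile (plate mean
#' plus drift) on the latent scale.
#'
#' @param design A [generate_design()] result.
#' @param specs A list of [antibody_spec()] objects (or a single one).
#' @param seed Integer seed; the same seed reproduces the table bit for bit.
#' @return A raw-stage [intensity_table()] covering study aliquots and
#'   reference wells, with the latent (pre-distortion) study values attached
#'   as attribute `"latent"` and reference-well IDs as attribute
#'   `"reference_ids"`.
#' @examples
#' d <- generate_design(2, 1, 0, 1, 96, 0, seed = 1)
#' sp <- antibody_spec("ab1",
#'   variance_components(var_H = 1, var_eps = 0.5), plate_means = 10)
#' sim <- simulate_intensities(d, list(sp), seed = 7)
#' @export
simulate_intensities <- function(design, specs, seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (inherits(specs, "antibody_spec")) specs <- list(specs)
  if (length(specs) < 1) stop("specs must be non-empty")
  a <- design$aliquots
  r <- design$reference_wells
  n_a <- nrow(a); n_r <- nrow(r)
  ids <- c(a$aliquot_id, r$aliquot_id)
  plate <- c(a$plate, r$plate)
  cwell <- centered_well(plate, c(a$well, r$well))

  # grouping labels for the study aliquots (reference wells have none)
  g <- list(
    H = a$pair_id,
    M = ifelse(a$zygosity == "MZ", a$pair_id, a$individual_id),
    E = a$individual_id,
    W = paste(a$pair_id, a$visit, sep = ":"),
    V = paste(a$individual_id, a$visit, sep = ":")
  )
  comp_for <- c(H = "var_H", M = "var_M", E = "var_E", W = "var_W",
                V = "var_V")

  with_local_seed(seed, {
    dil_z <- stats::rnorm(n_a + n_r)  # one dilution draw per aliquot
    latent_all <- raw_all <- matrix(
      NA_real_, n_a + n_r, length(specs),
      dimnames = list(ids, vapply(specs, `[[`, "", "antibody_id")))
    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      mu <- rep_len(sp$plate_means, design$n_plates)
      beta <- rep_len(sp$drift_slopes, design$n_plates)
      vc <- sp$components
      latent <- mu[plate] + beta[plate] * cwell
      eff <- numeric(n_a)
      for (nm in names(g)) {
        f <- factor(g[[nm]])
        u <- stats::rnorm(nlevels(f), sd = sqrt(vc[[comp_for[nm]]]))
        eff <- eff + u[as.integer(f)]
      }
      eff <- eff + stats::rnorm(n_a, sd = sqrt(vc[["var_eps"]]))
      latent[seq_len(n_a)] <- latent[seq_len(n_a)] + eff
      if (sp$boxcox_lambda != 0) {
        bad <- which(sp$boxcox_lambda * latent + 1 <= 0)
        if (length(bad))
          stop("inverse Box-Cox undefined for antibody ", sp$antibody_id,
               ", aliquot ", ids[bad[1]],
               " (latent value outside the transformation's domain)")
      }
      raw <- boxcox_inverse(latent, sp$boxcox_lambda) *
        exp(sp$dilution_sd * dil_z)
      latent_all[, s] <- latent
      raw_all[, s] <- raw
    }
    tab <- intensity_table(raw_all, "raw")
    attr(tab, "latent") <- latent_all[seq_len(n_a), , drop = FALSE]
    attr(tab, "reference_ids") <- r$aliquot_id
    tab
  })
}
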