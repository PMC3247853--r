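#' Default antibody generator specifications
#'
#' Builds a set of antibody specs whose variance proportions are drawn (with
#' replacement) from the published 66-antibody reference decomposition, so a
#' simulated cohort reproduces the observed spread of familial, biological
#' and experimental variance shares. Familial variance is generated as a
#' purely additive-genetic effect, i.e. split equally between the H and M
#' components. Latent totals are scaled to `total_variance`; raw intensities
#' are log-normal (Box-Cox lambda 0) around plate means on the log-MFI
#' scale.
#'
#' @param n_antibodies Number of specs to build.
#' @param n_plates Number of plates in the target design.
#' @param seed Integer seed for the reference-row draw.
#' @param total_variance Total latent variance per antibody (default 1).
#' @param plate_means Per-plate latent means; default log-MFI-scale means
#'   around 7 with 0.2 spacing.
#' @param dilution_sd SD of log dilution shared by all antibodies of an
#'   aliquot (default 0.15).
#' @param drift_slopes Per-plate well-drift slopes (default 0).
#' @param boxcox_lambda Raw-scale Box-Cox exponent (default 0).
#' @return A list of [antibody_spec()] objects.
#' @export
default_antibody_specs <- function(n_antibodies, n_plates, seed = 1,
                                   total_variance = 1,
                                   plate_means = NULL,
                                   dilution_sd = 0.15,
                                   drift_slopes = 0,
                                   boxcox_lambda = 0) {
  ref <- reference_variance_table()
  if (is.null(plate_means))
    plate_means <- 7 + 0.2 * (seq_len(n_plates) - (n_plates + 1) / 2)
  rows <- with_local_seed(seed, sample.int(nrow(ref), n_antibodies,
                                           replace = TRUE))
  lapply(seq_len(n_antibodies), function(i) {
    p <- ref[rows[i], ]
    tot <- p$fam + p$env + p$cv + p$iv + p$exp  # printed rows sum to ~100
    v <- total_variance / tot
    antibody_spec(
      antibody_id = sprintf("AB%03d", i),
      components = variance_components(
        var_H = v * p$fam / 2, var_M = v * p$fam / 2, var_E = v * p$env,
        var_W = v * p$cv, var_V = v * p$iv, var_eps = v * p$exp),
      plate_means = plate_means, drift_slopes = drift_slopes,
      boxcox_lambda = boxcox_lambda, dilution_sd = dilution_sd)
  })
}

#' Fit the twin model to every antibody of a transformed table
#'
#' @param transformed A transformed-stage [intensity_table()].
#' @param design The matching [generate_design()] result.
#' @param model `"auto"` (AIC selection between forms 1 and 2), `1`, or `2`.
#' @return Data frame with one row per antibody: selected model, both AICs
#'   (when `model = "auto"`), the six variance components, the proportion
#'   breakdown, log-likelihood and convergence flag.
#' @export
fit_all_antibodies <- function(transformed, design, model = "auto") {
  x <- transformed$values
  rows <- lapply(colnames(x), function(ab) {
    y <- stats::setNames(x[, ab], rownames(x))
    fit <- if (identical(model, "auto")) select_model(y, design)
           else fit_variance_model(y, design, model_form = as.integer(model))
    p <- variance_proportions(fit)
    data.frame(
      antibody_id = ab, model_selected = fit$model_form,
      aic_model1 = fit$aic_model1 %||% NA_real_,
      aic_model2 = fit$aic_model2 %||% NA_real_,
      var_H = fit$components[["var_H"]], var_M = fit$components[["var_M"]],
      var_E = fit$components[["var_E"]], var_W = fit$components[["var_W"]],
      var_V = fit$components[["var_V"]],
      var_eps = fit$components[["var_eps"]],
      fam = p$fam, env = p$env, cv = p$cv, iv = p$iv, exp = p$exp,
      fam_ne = p$fam_ne, env_ne = p$env_ne, cv_ne = p$cv_ne, iv_ne = p$iv_ne,
      loglik = fit$loglik, converged = fit$converged,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the whole pipeline: simulate (or ingest), preprocess, fit, summarize
#'
#' Executes the full workflow and writes every intermediate product into
#' `out_dir`: the metadata/raw-intensity CSV pair, the transformed
#' intensities, the outlier report, before/after replicate concordance, the
#' per-antibody results table, the cohort summary, and a run log recording
#' the seed and package version. Identical config and seed give identical
#' outputs.
#'
#' @param config A list, or path to a YAML file, with optional entries
#'   `cohort` (arguments of [generate_design()]), `antibodies` (arguments of
#'   [default_antibody_specs()] other than `n_plates`/`seed`), `input`
#'   (list with `metadata` and `intensities` CSV paths — when present the
#'   generator is skipped), `alpha` (outlier tail probability, default
#'   1e-4) and `model` (`"auto"`, 1 or 2).
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the results data frame, the cohort
#'   summary, the preprocessing products, and the design.
#' @export
run_all <- function(config = list(), seed = 1, out_dir = tempfile("twinvar")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("twinvar %s", as.character(utils::packageVersion("twinvar"))),
                 sprintf("R %s", getRversion()), sprintf("seed %d", seed))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$input)) {
    design <- stage("ingest", design_from_metadata(config$input$metadata))
    raw <- stage("ingest", read_intensity_csv(config$input$intensities, "raw"))
    log_lines <- c(log_lines, sprintf("ingested %s", config$input$intensities))
  } else {
    design <- stage("simulate",
      do.call(generate_design, c(config$cohort %||% list(),
                                 list(seed = seed))))
    ab_args <- config$antibodies %||% list()
    ab_args$n_antibodies <- ab_args$n_antibodies %||% 10
    ab_args$n_plates <- design$n_plates
    ab_args$seed <- seed + 1L
    specs <- stage("simulate", do.call(default_antibody_specs, ab_args))
    raw <- stage("simulate", simulate_intensities(design, specs,
                                                  seed = seed + 2L))
    log_lines <- c(log_lines, sprintf("simulated %d antibodies", length(specs)))
  }
  write_cohort_csvs(design, raw, out_dir)
  log_lines <- c(log_lines,
    sprintf("design: %d aliquots on %d plates", nrow(design$aliquots),
            design$n_plates))

  alpha <- config$alpha %||% 1e-4
  prep <- stage("preprocess", preprocess_pipeline(raw, design, alpha = alpha))
  write_cohort_csvs(design, prep$transformed, out_dir)
  utils::write.csv(
    data.frame(aliquot_id = names(prep$outliers$distance),
               distance = prep$outliers$distance,
               flagged = names(prep$outliers$distance) %in%
                 prep$outliers$flagged, row.names = NULL),
    file.path(out_dir, "outliers.csv"), row.names = FALSE)
  if (!is.null(prep$concordance_before)) {
    utils::write.csv(
      data.frame(antibody_id = names(prep$concordance_before$r),
                 r_before = prep$concordance_before$r,
                 r_after = prep$concordance_after$r, row.names = NULL),
      file.path(out_dir, "concordance.csv"), row.names = FALSE)
  }
  log_lines <- c(log_lines,
    sprintf("preprocess: %d outliers flagged, %d aliquots retained",
            length(prep$outliers$flagged), nrow(prep$transformed$values)))

  results <- stage("fit", fit_all_antibodies(prep$transformed, design,
                                             model = config$model %||% "auto"))
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  summary_df <- stage("summarize", cohort_summary(results))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("fit: %d antibodies", nrow(results)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(design = design, preprocess = prep, results = results,
                 summary = summary_df, out_dir = out_dir))
}
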