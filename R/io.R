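#' Write a design and intensity table as a CSV pair
#'
#' Writes `metadata.csv` (one row per occupied well: aliquot_id, pair_id,
#' individual_id, zygosity, visit, replicate, plate, well; reference wells
#' carry empty individual fields) and `intensities_<stage>.csv` (aliquot_id
#' plus one column per antibody).
#'
#' @param design A [generate_design()] result.
#' @param table An [intensity_table()]; its rows must cover the design.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_cohort_csvs <- function(design, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- design$aliquots
  meta <- data.frame(aliquot_id = a$aliquot_id, pair_id = a$pair_id,
                     individual_id = a$individual_id, zygosity = a$zygosity,
                     visit = a$visit, replicate = a$replicate,
                     plate = a$plate, well = a$well,
                     stringsAsFactors = FALSE)
  r <- design$reference_wells
  if (nrow(r)) {
    meta <- rbind(meta, data.frame(
      aliquot_id = r$aliquot_id, pair_id = "", individual_id = "",
      zygosity = "", visit = NA_integer_, replicate = NA_integer_,
      plate = r$plate, well = r$well, stringsAsFactors = FALSE))
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  x <- table$values
  int_path <- file.path(dir, paste0("intensities_", table$stage, ".csv"))
  utils::write.csv(data.frame(aliquot_id = rownames(x), x,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   int_path, row.names = FALSE, quote = FALSE)
  invisible(c(metadata = meta_path, intensities = int_path))
}

#' Rebuild a cohort design from a metadata CSV
#'
#' Inverse of the metadata half of [write_cohort_csvs()]: reconstructs the
#' pairs / individuals / samples / aliquots / reference-wells structure from
#' a long-format metadata table, so externally supplied data can enter the
#' pipeline in place of the simulator.
#'
#' @param meta Data frame with the columns written by [write_cohort_csvs()],
#'   or a path to such a CSV.
#' @param plate_capacity Wells per plate (default 96).
#' @return A `cohort_design` object.
#' @export
design_from_metadata <- function(meta, plate_capacity = 96) {
  if (is.character(meta)) meta <- utils::read.csv(meta,
                                                  stringsAsFactors = FALSE)
  need <- c("aliquot_id", "pair_id", "individual_id", "zygosity", "visit",
            "replicate", "plate", "well")
  stopifnot(all(need %in% names(meta)))
  is_ref <- is.na(meta$visit) | meta$pair_id == ""
  a <- meta[!is_ref, need]
  a$sample_id <- sprintf("%s.V%d", a$individual_id, a$visit)
  pairs <- unique(a[, c("pair_id", "zygosity")])
  pairs <- pairs[order(pairs$pair_id), ]
  individuals <- unique(a[, c("individual_id", "pair_id")])
  individuals <- individuals[order(individuals$individual_id), ]
  samples <- unique(a[, c("sample_id", "individual_id", "visit")])
  rownames(pairs) <- rownames(individuals) <- rownames(samples) <-
    rownames(a) <- NULL
  structure(
    list(pairs = pairs, individuals = individuals, samples = samples,
         aliquots = a[, c("aliquot_id", "sample_id", "individual_id",
                          "pair_id", "zygosity", "visit", "replicate",
                          "plate", "well")],
         reference_wells = data.frame(
           aliquot_id = meta$aliquot_id[is_ref],
           plate = meta$plate[is_ref], well = meta$well[is_ref],
           stringsAsFactors = FALSE),
         n_plates = max(meta$plate), plate_capacity = plate_capacity),
    class = "cohort_design")
}

#' Read an intensity CSV written by [write_cohort_csvs()]
#'
#' @param path CSV path with an `aliquot_id` column and one column per
#'   antibody.
#' @param stage Processing stage tag of the stored values.
#' @return An [intensity_table()].
#' @export
read_intensity_csv <- function(path, stage = "raw") {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "aliquot_id"), drop = FALSE])
  rownames(m) <- d$aliquot_id
  intensity_table(m, stage)
}
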