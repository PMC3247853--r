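#' Generate a longitudinal twin-cohort sampling design
#'
#' Constructs the full sampling structure of a two-visit twin study with
#' duplicate aliquots randomised onto multi-well assay plates: twin pairs
#' (monozygotic or dizygotic), individuals, per-visit serum samples, sample
#' aliquots, and per-plate reference wells. All individuals are sampled at
#' visit 1; both members of the first `n_revisit_mz_pairs` MZ pairs re-attend
#' for visit 2 (twins attend in pairs, so visit sets are identical within a
#' pair); the visit-1 sample of each individual in the first
#' `n_duplicated_mz_pairs` MZ pairs is split into two aliquots. Aliquots are
#' placed onto plates by a single seeded uniform permutation over the
#' non-reference wells; the last `n_reference_wells_per_plate` well positions
#' of each plate hold reference-sample aliquots not linked to any individual.
#'
#' The default arguments reproduce the design of a published longitudinal
#' twin serum study: 56 MZ and 21 DZ pairs (154 individuals), 34 MZ pairs
#' re-attending (222 samples), 24 MZ pairs with duplicated visit-1 samples
#' (270 aliquots), on three 96-well plates with 6 reference wells each
#' (288 occupied wells).
#'
#' @param n_mz_pairs,n_dz_pairs Number of monozygotic / dizygotic twin pairs.
#' @param n_revisit_mz_pairs Number of MZ pairs (both twins) sampled again at
#'   visit 2. Must not exceed `n_mz_pairs`.
#' @param n_duplicated_mz_pairs Number of MZ pairs whose visit-1 samples are
#'   each split into two aliquots. Must not exceed `n_mz_pairs`.
#' @param plate_capacity Wells per plate (default 96).
#' @param n_reference_wells_per_plate Reference wells reserved per plate.
#' @param seed Integer seed controlling the plate/well randomisation; the
#'   same seed always yields the same design.
#' @param n_plates Optional fixed plate count. If `NULL` (default) the
#'   smallest count that holds all aliquots is used; if supplied and too
#'   small, an error states the required count.
#'
#' @return An object of class `cohort_design`: a list with data frames
#'   `pairs` (pair_id, zygosity), `individuals` (individual_id, pair_id),
#'   `samples` (sample_id, individual_id, visit), `aliquots` (aliquot_id,
#'   sample_id, individual_id, pair_id, zygosity, visit, replicate, plate,
#'   well) and `reference_wells` (aliquot_id, plate, well), plus `n_plates`
#'   and `plate_capacity`.
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d$samples)   # 222
#' nrow(d$aliquots)  # 270
#' @export
generate_design <- function(n_mz_pairs = 56, n_dz_pairs = 21,
                            n_revisit_mz_pairs = 34,
                            n_duplicated_mz_pairs = 24,
                            plate_capacity = 96,
                            n_reference_wells_per_plate = 6,
                            seed = 1L, n_plates = NULL) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_mz_pairs + n_dz_pairs >= 1,
            plate_capacity >= 1, n_reference_wells_per_plate >= 0)
  if (n_revisit_mz_pairs > n_mz_pairs)
    stop("n_revisit_mz_pairs (", n_revisit_mz_pairs,
         ") exceeds the number of MZ pairs (", n_mz_pairs, ")")
  if (n_duplicated_mz_pairs > n_mz_pairs)
    stop("n_duplicated_mz_pairs (", n_duplicated_mz_pairs,
         ") exceeds the number of MZ pairs (", n_mz_pairs, ")")
  usable <- plate_capacity - n_reference_wells_per_plate
  if (usable < 1)
    stop("plate_capacity must exceed n_reference_wells_per_plate")

  n_pairs <- n_mz_pairs + n_dz_pairs
  pair_id <- sprintf("P%03d", seq_len(n_pairs))
  zygosity <- rep(c("MZ", "DZ"), c(n_mz_pairs, n_dz_pairs))
  pairs <- data.frame(pair_id = pair_id, zygosity = zygosity,
                      stringsAsFactors = FALSE)

  individuals <- data.frame(
    individual_id = sprintf("%s.%d", rep(pair_id, each = 2), rep(1:2, n_pairs)),
    pair_id = rep(pair_id, each = 2),
    stringsAsFactors = FALSE
  )

  # visit 1 for everyone; visit 2 for both members of the revisiting MZ pairs
  revisit_pairs <- pair_id[seq_len(n_revisit_mz_pairs)]
  v2_ind <- individuals$individual_id[individuals$pair_id %in% revisit_pairs]
  samples <- rbind(
    data.frame(individual_id = individuals$individual_id, visit = 1L,
               stringsAsFactors = FALSE),
    if (length(v2_ind)) data.frame(individual_id = v2_ind, visit = 2L,
                                   stringsAsFactors = FALSE)
  )
  samples$sample_id <- sprintf("%s.V%d", samples$individual_id, samples$visit)
  samples <- samples[, c("sample_id", "individual_id", "visit")]

  # aliquots: every sample once; visit-1 samples of duplicated pairs twice
  dup_pairs <- pair_id[seq_len(n_duplicated_mz_pairs)]
  dup_ind <- individuals$individual_id[individuals$pair_id %in% dup_pairs]
  n_rep <- ifelse(samples$visit == 1L & samples$individual_id %in% dup_ind,
                  2L, 1L)
  aliquots <- samples[rep(seq_len(nrow(samples)), n_rep), ]
  aliquots$replicate <- unlist(lapply(n_rep, seq_len), use.names = FALSE)
  aliquots$aliquot_id <- sprintf("%s.R%d", aliquots$sample_id,
                                 aliquots$replicate)
  idx <- match(aliquots$individual_id, individuals$individual_id)
  aliquots$pair_id <- individuals$pair_id[idx]
  aliquots$zygosity <- pairs$zygosity[match(aliquots$pair_id, pairs$pair_id)]

  n_aliquots <- nrow(aliquots)
  need_plates <- ceiling(n_aliquots / usable)
  if (is.null(n_plates)) {
    n_plates <- need_plates
  } else if (n_plates < need_plates) {
    stop(n_aliquots, " aliquots do not fit on ", n_plates, " plate(s) with ",
         usable, " usable wells each; ", need_plates, " plate(s) required")
  }

  # single seeded uniform permutation of aliquots over non-reference wells;
  # reference wells sit at the last positions of each plate
  ref_wells <- if (n_reference_wells_per_plate > 0) {
    data.frame(
      aliquot_id = sprintf("REF.P%d.W%02d",
                           rep(seq_len(n_plates),
                               each = n_reference_wells_per_plate),
                           rep(seq(usable + 1L, plate_capacity), n_plates)),
      plate = rep(seq_len(n_plates), each = n_reference_wells_per_plate),
      well = rep(seq(usable + 1L, plate_capacity), n_plates),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(aliquot_id = character(), plate = integer(), well = integer())
  }

  open_wells <- data.frame(
    plate = rep(seq_len(n_plates), each = usable),
    well = rep(seq_len(usable), n_plates)
  )
  perm <- with_local_seed(seed, sample.int(n_aliquots))
  slot <- integer(n_aliquots)
  slot[perm] <- seq_len(n_aliquots)  # permuted aliquots fill wells in order
  aliquots$plate <- open_wells$plate[slot]
  aliquots$well <- open_wells$well[slot]
  aliquots <- aliquots[, c("aliquot_id", "sample_id", "individual_id",
                           "pair_id", "zygosity", "visit", "replicate",
                           "plate", "well")]
  rownames(aliquots) <- NULL

  structure(
    list(pairs = pairs, individuals = individuals, samples = samples,
         aliquots = aliquots, reference_wells = ref_wells,
         n_plates = n_plates, plate_capacity = plate_capacity),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Twin cohort design:",
      sum(x$pairs$zygosity == "MZ"), "MZ +",
      sum(x$pairs$zygosity == "DZ"), "DZ pairs;",
      nrow(x$individuals), "individuals;",
      nrow(x$samples), "samples;",
      nrow(x$aliquots), "aliquots on", x$n_plates, "plate(s) (",
      nrow(x$reference_wells), "reference wells)\n")
  invisible(x)
}

#' Validate the structural invariants of a cohort design
#'
#' Checks that every individual belongs to exactly one pair, each pair has two
#' members, co-twins share identical visit sets, each aliquot occupies a
#' unique plate/well, and well indices respect the plate capacity.
#'
#' @param design A [generate_design()] result.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  a <- design$aliquots
  if (any(table(design$individuals$pair_id) != 2))
    stop("each pair must have exactly 2 individuals")
  vs <- split(design$samples$visit, design$samples$individual_id)
  ip <- split(design$individuals$individual_id, design$individuals$pair_id)
  for (p in names(ip)) {
    v1 <- sort(vs[[ip[[p]][1]]]); v2 <- sort(vs[[ip[[p]][2]]])
    if (!identical(v1, v2)) stop("co-twins of pair ", p,
                                 " have different visit sets")
  }
  occ <- rbind(a[, c("plate", "well")],
               design$reference_wells[, c("plate", "well")])
  if (anyDuplicated(occ)) stop("duplicated plate/well assignment")
  if (any(occ$well > design$plate_capacity) || any(occ$well < 1))
    stop("well index outside plate capacity")
  invisible(TRUE)
}

# run an expression under a temporary RNG state so package functions never
# disturb the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
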