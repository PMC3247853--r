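small_cfg <- list(
  cohort = list(n_mz_pairs = 12, n_dz_pairs = 5, n_revisit_mz_pairs = 6,
                n_duplicated_mz_pairs = 5, plate_capacity = 96,
                n_reference_wells_per_plate = 2),
  antibodies = list(n_antibodies = 4)
)

test_that("the full workflow writes one result row per antibody", {
  out <- run_all(small_cfg, seed = 11, out_dir = tempfile("run"))
  expect_equal(nrow(out$results), 4)
  expect_true(all(out$results$converged))
  files <- list.files(out$out_dir)
  for (f in c("metadata.csv", "intensities_raw.csv",
              "intensities_transformed.csv", "outliers.csv",
              "concordance.csv", "results.csv", "summary.csv",
              "run_log.txt"))
    expect_true(f %in% files)
  expect_true(all(c("fam", "exp", "stable") %in% out$summary$component))
})

test_that("identical config and seed give byte-identical results", {
  d1 <- tempfile("runA"); d2 <- tempfile("runB")
  run_all(small_cfg, seed = 12, out_dir = d1)
  run_all(small_cfg, seed = 12, out_dir = d2)
  for (f in c("results.csv", "summary.csv", "intensities_raw.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("supplying input CSVs skips the generator", {
  sim_dir <- tempfile("sim")
  out1 <- run_all(small_cfg, seed = 13, out_dir = sim_dir)
  cfg2 <- list(input = list(
    metadata = file.path(sim_dir, "metadata.csv"),
    intensities = file.path(sim_dir, "intensities_raw.csv")))
  out2 <- run_all(cfg2, seed = 99, out_dir = tempfile("ingest"))
  # ingested run reproduces the simulated run's fits (data identical)
  expect_equal(out2$results$fam, out1$results$fam, tolerance = 1e-6)
  log <- readLines(file.path(out2$out_dir, "run_log.txt"))
  expect_true(any(grepl("ingested", log)))
})

test_that("round-tripping a design through metadata CSVs preserves structure", {
  d <- tiny_design()
  raw <- simulate_intensities(
    d, default_antibody_specs(2, d$n_plates, seed = 14), seed = 15)
  dir <- tempfile("rt")
  write_cohort_csvs(d, raw, dir)
  d2 <- design_from_metadata(file.path(dir, "metadata.csv"))
  expect_equal(d2$aliquots$aliquot_id, d$aliquots$aliquot_id)
  expect_equal(d2$aliquots$well, d$aliquots$well)
  expect_equal(nrow(d2$reference_wells), nrow(d$reference_wells))
  expect_equal(d2$pairs$zygosity[order(d2$pairs$pair_id)],
               d$pairs$zygosity[order(d$pairs$pair_id)])
  raw2 <- read_intensity_csv(file.path(dir, "intensities_raw.csv"))
  expect_equal(raw2$values, raw$values, tolerance = 1e-12)
})
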