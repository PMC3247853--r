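test_that("noise-free simulation reduces to the inverse Box-Cox of the plate mean", {
  d <- tiny_design()
  sp <- antibody_spec("a", variance_components(), plate_means = 5,
                      boxcox_lambda = 1)
  s <- simulate_intensities(d, list(sp), seed = 1)
  expect_true(all(abs(s$values - 6) < 1e-12))  # inverse of (x-1)/1 at 5
  expect_identical(s$stage, "raw")
})

test_that("A/D/C variances convert to the identifiable H/M pair", {
  vc <- variance_components(var_A = 0.4, var_D = 0.2, var_C = 0.1,
                            var_E = 0.3)
  expect_equal(vc[["var_H"]], 0.4 / 2 + 0.2 / 4 + 0.1)
  expect_equal(vc[["var_M"]], 0.4 / 2 + 3 * 0.2 / 4)
  expect_error(variance_components(var_H = 1, var_A = 1), "not both")
  expect_error(variance_components(var_E = -1), ">= 0")
})

test_that("simulated co-twin covariances obey the MZ and DZ identities", {
  vc <- variance_components(var_H = .3, var_M = .2, var_E = .25, var_W = .15,
                            var_V = .1, var_eps = .2)
  co_twin_cov <- function(n_mz, n_dz, seed) {
    d <- generate_design(n_mz, n_dz, 0, 0, 96, 0, seed = seed)
    lat <- simulate_latent(d, vc, seed + 1, plate_means = 0)
    a <- d$aliquots[match(names(lat), d$aliquots$aliquot_id), ]
    ord <- order(a$pair_id, a$individual_id)
    m <- matrix(lat[ord], ncol = 2, byrow = TRUE)
    zyg <- a$zygosity[ord][seq(1, length(ord), 2)]
    list(mz = if (any(zyg == "MZ")) cov(m[zyg == "MZ", 1], m[zyg == "MZ", 2]),
         dz = if (any(zyg == "DZ")) cov(m[zyg == "DZ", 1], m[zyg == "DZ", 2]),
         tot = var(as.vector(m)))
  }
  cc <- co_twin_cov(4000, 4000, 21)
  # MC standard error of a sample covariance of bivariate normals
  se <- function(v1, v2, cv, n) sqrt((v1 * v2 + cv^2) / (n - 1))
  tot <- sum(vc)
  expect_lt(abs(cc$mz - (.3 + .2 + .15)), 3 * se(tot, tot, .65, 4000))
  expect_lt(abs(cc$dz - (.3 + .15)), 3 * se(tot, tot, .45, 4000))
  expect_lt(abs(cc$tot - tot), 4 * tot / sqrt(4000))
})

test_that("stable components drive the within-individual across-visit covariance", {
  vc <- variance_components(var_H = .3, var_M = .2, var_E = .25, var_W = .15,
                            var_V = .1, var_eps = .2)
  d <- generate_design(4000, 1, 4000, 0, 96, 0, seed = 31)
  lat <- simulate_latent(d, vc, 32, plate_means = 0)
  a <- d$aliquots[match(names(lat), d$aliquots$aliquot_id), ]
  mz <- a[a$zygosity == "MZ", ]
  ord <- order(mz$individual_id, mz$visit)
  m <- matrix(lat[mz$aliquot_id][ord], ncol = 2, byrow = TRUE)
  expect_lt(abs(cov(m[, 1], m[, 2]) - (.3 + .2 + .25)), 0.05)
})

test_that("duplicate aliquots share everything but the residual", {
  vc <- variance_components(var_H = .3, var_M = .2, var_E = .25, var_W = .15,
                            var_V = .1, var_eps = .2)
  d <- generate_design(4000, 1, 0, 4000, 96, 0, seed = 41)
  lat <- simulate_latent(d, vc, 42, plate_means = 0)
  map <- duplicate_map(d)
  expect_lt(abs(cov(lat[map$aliquot_1], lat[map$aliquot_2]) -
                  (sum(vc) - .2)), 0.05)
})

test_that("the same seed reproduces the raw table bit for bit", {
  d <- tiny_design()
  specs <- default_antibody_specs(3, d$n_plates, seed = 2)
  expect_identical(simulate_intensities(d, specs, seed = 5)$values,
                   simulate_intensities(d, specs, seed = 5)$values)
  expect_false(identical(simulate_intensities(d, specs, seed = 5)$values,
                         simulate_intensities(d, specs, seed = 6)$values))
})

test_that("latent values outside the inverse Box-Cox domain are rejected", {
  d <- tiny_design()
  sp <- antibody_spec("bad", variance_components(var_eps = 25),
                      plate_means = 0, boxcox_lambda = 1)
  expect_error(simulate_intensities(d, list(sp), seed = 3),
               "inverse Box-Cox undefined for antibody bad")
})

test_that("a common dilution factor is shared across antibodies of an aliquot", {
  d <- tiny_design()
  vc <- variance_components(var_eps = 0.1)
  specs <- list(antibody_spec("a1", vc, 5, dilution_sd = 0.5),
                antibody_spec("a2", vc, 8, dilution_sd = 0.5))
  s <- simulate_intensities(d, specs, seed = 11)
  lat <- attr(s, "latent")
  f1 <- s$values[seq_len(nrow(lat)), 1] / exp(lat[, 1])
  f2 <- s$values[seq_len(nrow(lat)), 2] / exp(lat[, 2])
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_gt(sd(log(f1)), 0.2)
})
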