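# Shared fixtures and independent oracles for the test suite.

# small mixed-zygosity design: 2 MZ + 1 DZ pairs, 1 revisiting MZ pair,
# 1 duplicated MZ pair -> 3 pairs are not enough for estimation but exercise
# every structural feature (8 individuals would need 4 pairs; here 6)
tiny_design <- function(seed = 4) {
  generate_design(n_mz_pairs = 2, n_dz_pairs = 1, n_revisit_mz_pairs = 1,
                  n_duplicated_mz_pairs = 1, plate_capacity = 20,
                  n_reference_wells_per_plate = 2, seed = seed)
}

# independently coded dense Gaussian log-likelihood with GLS-profiled fixed
# effects; builds the covariance from first principles (shared-label
# indicators per random effect), not via the package's blockwise path
dense_loglik <- function(design, y, X, v) {
  a <- design$aliquots[match(names(y), design$aliquots$aliquot_id), ]
  lab <- list(a$pair_id,
              ifelse(a$zygosity == "MZ", a$pair_id, a$individual_id),
              a$individual_id,
              paste(a$pair_id, a$visit),
              paste(a$individual_id, a$visit))
  n <- length(y)
  S <- diag(v[6], n)
  for (i in 1:5) S <- S + v[i] * outer(lab[[i]], lab[[i]], "==")
  Si <- solve(S)
  b <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(r) %*% Si %*% r))
}

# simulate one antibody and return its latent values named by aliquot
simulate_latent <- function(design, vc, seed, plate_means = 7,
                            drift_slopes = 0, dilution_sd = 0) {
  sm <- simulate_intensities(
    design,
    list(antibody_spec("ab", vc, plate_means, drift_slopes = drift_slopes,
                       boxcox_lambda = 0, dilution_sd = dilution_sd)),
    seed = seed)
  lat <- attr(sm, "latent")[, 1]
  names(lat) <- rownames(sm$values)[seq_along(lat)]
  lat
}
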