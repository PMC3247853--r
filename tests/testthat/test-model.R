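test_that("blockwise likelihood equals the dense Gaussian likelihood", {
  d <- tiny_design()
  g <- build_grouping(d)
  set.seed(81)
  y <- setNames(rnorm(nrow(g)), rownames(g))
  for (form in 1:2) {
    X <- twinvar:::fixed_design_matrix(g, form)
    bp <- twinvar:::build_block_patterns(g, X, as.vector(y))
    for (i in 1:10) {
      v <- runif(6, 0.05, 2)
      expect_equal(twinvar:::profile_loglik(bp, v)$loglik,
                   dense_loglik(d, y, X, v), tolerance = 1e-8)
    }
  }
})

test_that("a residual-only antibody is pushed to the boundary", {
  d <- generate_design(30, 12, 15, 10, 96, 0, seed = 82)
  lat <- simulate_latent(d, variance_components(var_eps = 1), 83)
  fit <- fit_variance_model(lat, d, 1)
  p <- variance_proportions(fit)
  expect_gt(p$exp, 97)
  expect_lt(sum(fit$components[1:5]), 0.05 * fit$components[["var_eps"]])
})

test_that("the ML solution dominates the truth and every start point", {
  d <- generate_design(25, 10, 12, 8, 96, 0, seed = 84)
  truth <- variance_components(var_H = .2, var_M = .1, var_E = .2,
                               var_W = .05, var_V = .1, var_eps = .35)
  lat <- simulate_latent(d, truth, 85)
  fit <- fit_variance_model(lat, d, 1)
  g <- build_grouping(d, names(lat))
  X <- twinvar:::fixed_design_matrix(g, 1)
  bp <- twinvar:::build_block_patterns(g, X, as.vector(lat))
  ll_at <- function(v) twinvar:::profile_loglik(bp, v)$loglik
  expect_gte(fit$loglik + 1e-6, ll_at(as.vector(unclass(truth))))
  v0 <- mean(lm.fit(X, as.vector(lat))$residuals^2)
  for (pr in list(rep(1/6, 6), c(.04,.04,.04,.04,.04,.8)))
    expect_gte(fit$loglik + 1e-6, ll_at(pr * v0))
})

test_that("estimates are exactly scale-equivariant and AIC obeys its identity", {
  d <- generate_design(15, 6, 8, 5, 96, 0, seed = 86)
  lat <- simulate_latent(d, variance_components(var_H = .3, var_E = .2,
                                                var_V = .1, var_eps = .4), 87)
  f1 <- fit_variance_model(lat, d, 1)
  a <- 3.7; b <- -2.2
  f2 <- fit_variance_model(a * lat + b, d, 1)
  expect_equal(unclass(f2$components), a^2 * unclass(f1$components),
               tolerance = 1e-6)
  p1 <- variance_proportions(f1); p2 <- variance_proportions(f2)
  expect_equal(unlist(p1[1:5]), unlist(p2[1:5]), tolerance = 1e-6)
  for (f in list(f1, f2)) {
    expect_identical(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$k, f$n_plates + 6)
  }
})

test_that("estimates agree with an established mixed-model fitter", {
  d <- generate_design(20, 8, 10, 6, 48, 0, seed = 88)  # 2 plates
  truth <- variance_components(var_H = .25, var_M = .15, var_E = .2,
                               var_W = .1, var_V = .15, var_eps = .3)
  lat <- simulate_latent(d, truth, 89)
  ours <- fit_variance_model(lat, d, 1)
  g <- build_grouping(d, names(lat))
  df <- data.frame(y = as.vector(lat), plate = factor(g$plate),
                   H = g$H, M = g$M, E = g$E, W = g$W, V = g$V)
  lf <- lme4::lmer(
    y ~ 0 + plate + (1 | H) + (1 | M) + (1 | E) + (1 | W) + (1 | V),
    data = df, REML = FALSE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  expect_equal(ours$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  vcl <- as.data.frame(lme4::VarCorr(lf))
  lv <- setNames(vcl$vcov, vcl$grp)
  expect_equal(unname(unclass(ours$components)),
               unname(lv[c("H", "M", "E", "W", "V", "Residual")]),
               tolerance = 1e-3)
})

test_that("AIC selection prefers the generating model form", {
  d <- generate_design(25, 10, 12, 8, 96, 0, seed = 90)
  vc <- variance_components(var_H = .2, var_M = .1, var_E = .2, var_W = .05,
                            var_V = .1, var_eps = .35)
  # strong drift: slope * well range comparable to twice the total SD
  slope <- 2 * sqrt(sum(vc)) / 96
  lat <- simulate_latent(d, vc, 91, drift_slopes = slope)
  sel <- select_model(lat, d)
  expect_identical(sel$model_form, 2)
  expect_lt(sel$aic_model2, sel$aic_model1)
  expect_equal(sel$k, 2 * sel$n_plates + 6)
  # formula sanity: k = 9, lnL = 0 -> AIC 18
  expect_equal(2 * 9 - 2 * 0, 18)
})

test_that("with MZ pairs only the likelihood is flat along var_H + var_M", {
  d <- generate_design(6, 2, 3, 2, 96, 0, seed = 92)
  g <- build_grouping(d)
  gm <- g[g$zygosity == "MZ", ]
  class(gm) <- class(g)
  set.seed(93)
  y <- rnorm(nrow(gm))
  X <- twinvar:::fixed_design_matrix(gm, 1)
  bp <- twinvar:::build_block_patterns(gm, X, y)
  base <- c(.4, .2, .3, .1, .1, .5)
  ll <- twinvar:::profile_loglik(bp, base)$loglik
  for (delta in c(-0.15, 0.1, 0.2)) {
    shifted <- base + c(delta, -delta, 0, 0, 0, 0)
    expect_equal(twinvar:::profile_loglik(bp, shifted)$loglik, ll,
                 tolerance = 1e-10)
  }
})

test_that("proportion breakdowns satisfy their arithmetic identities", {
  vc <- variance_components(var_H = 0.1565, var_M = 0.1565, var_E = 0.007,
                            var_V = 0.18, var_eps = 0.499)
  p <- variance_proportions(vc)
  # printed percentages (the published row sums to 99.9 before rounding)
  expect_equal(round(unlist(p[1:5]), 1),
               c(fam = 31.3, env = 0.7, cv = 0, iv = 18, exp = 49.9))
  expect_equal(p$fam + p$env + p$cv + p$iv + p$exp, 100, tolerance = 1e-6)
  expect_equal(p$fam_ne + p$env_ne + p$cv_ne + p$iv_ne, 100,
               tolerance = 1e-6)
  # residual-only breakdown
  pe <- variance_proportions(variance_components(var_eps = 2))
  expect_equal(unlist(pe[1:5]), c(fam = 0, env = 0, cv = 0, iv = 0,
                                  exp = 100))
  expect_true(all(is.na(unlist(pe[6:9]))))
  # equal components
  pq <- variance_proportions(variance_components(1, 1, 1, 1, 1, 1))
  expect_equal(round(pq$fam, 2), 33.33)
  expect_equal(round(c(pq$env, pq$cv, pq$iv, pq$exp), 2), rep(16.67, 4))
  expect_error(variance_proportions(variance_components()), "zero")
})
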