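dup_table <- function(v1, v2, extra_col = NULL) {
  n <- length(v1)
  m <- cbind(k1 = c(v1, v2), k2 = extra_col %||% c(v1, v2) + 10)
  rownames(m) <- c(paste0("s", 1:n, ".R1"), paste0("s", 1:n, ".R2"))
  list(table = intensity_table(m, "raw"),
       map = data.frame(sample_id = paste0("s", 1:n),
                        aliquot_1 = paste0("s", 1:n, ".R1"),
                        aliquot_2 = paste0("s", 1:n, ".R2")))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical replicates give r = 1, rank reversal gives r = -1", {
  v <- c(3, 1, 4, 1.5, 9)
  x <- dup_table(v, v)
  res <- replicate_concordance(x$table, x$map)
  expect_equal(unname(res$r), c(1, 1))
  expect_equal(res$median, 1)
  rev <- dup_table(v, max(v) + min(v) - v)  # order-reversing, still positive
  expect_equal(unname(replicate_concordance(rev$table, rev$map)$r[1]), -1)
})

test_that("Spearman r is invariant under strictly monotone transformations", {
  set.seed(12)
  v1 <- exp(rnorm(10)); v2 <- v1 + rnorm(10, sd = 0.3) + 3
  base <- dup_table(v1, v2)
  r0 <- replicate_concordance(base$table, base$map)$r[["k1"]]
  for (f in list(function(x) x^3, function(x) log(x + 10), sqrt)) {
    tr <- dup_table(f(v1), f(v2))
    expect_equal(replicate_concordance(tr$table, tr$map)$r[["k1"]], r0)
  }
})

test_that("constant replicate vectors are reported NA and excluded from the median", {
  x <- dup_table(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.4),
                 extra_col = rep(5, 8))
  res <- replicate_concordance(x$table, x$map)
  expect_true(is.na(res$r[["k2"]]))
  expect_equal(res$median, res$r[["k1"]])
})

test_that("fewer than 3 complete duplicate pairs is an error", {
  x <- dup_table(c(1, 2), c(1, 2))
  expect_error(replicate_concordance(x$table, x$map), "at least 3")
})

test_that("residual noise drives replicate concordance between its limits", {
  d <- generate_design(30, 1, 0, 30, 96, 0, seed = 51)
  base <- c(var_H = .3, var_M = .2, var_E = .25, var_W = .1, var_V = .1)
  noisy <- simulate_intensities(d, lapply(1:4, function(i) antibody_spec(
    paste0("n", i), do.call(variance_components, as.list(c(base, var_eps = 50))),
    7, boxcox_lambda = 0)), seed = 52)
  clean <- simulate_intensities(d, lapply(1:4, function(i) antibody_spec(
    paste0("c", i), do.call(variance_components, as.list(c(base, var_eps = 0))),
    7, boxcox_lambda = 0)), seed = 53)
  map <- duplicate_map(d)
  expect_lt(abs(replicate_concordance(noisy, map)$median), 0.25)
  expect_equal(replicate_concordance(clean, map)$median, 1)
})
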