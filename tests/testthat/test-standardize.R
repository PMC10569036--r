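mk_fp <- function(values, id = "A", solvents = NULL) {
  if (is.null(solvents)) solvents = paste0("s", seq_along(values))
  tibble::tibble(compound_id = id, solvent = solvents, value = values,
                 imputed = FALSE, standardized = FALSE)
}

test_that("standardization z-scores per compound with population variance", {
  out <- standardize_fingerprints(mk_fp(c(1, 2, 3)))
  expect_equal(out$value, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(round(out$value, 4), c(-1.2247, 0, 1.2247))
  expect_true(all(out$standardized))

  set.seed(8)
  x <- rnorm(10, 2, 1.5)
  std <- standardize_fingerprints(mk_fp(x))$value
  expect_lt(abs(mean(std)), 1e-9)
  expect_lt(abs(mean(std^2) - 1), 1e-9)
})

test_that("standardization cancels additive offsets and positive scalings", {
  set.seed(9)
  x <- rnorm(10)
  base <- standardize_fingerprints(mk_fp(x))$value
  # an ionization offset log10(f_u) shifts every solvent equally
  expect_equal(standardize_fingerprints(mk_fp(x + 0.7))$value, base,
               tolerance = 1e-12)
  expect_equal(standardize_fingerprints(mk_fp(3 * x - 1))$value, base,
               tolerance = 1e-12)
  # idempotence
  once <- standardize_fingerprints(mk_fp(x))
  expect_equal(standardize_fingerprints(once)$value, once$value,
               tolerance = 1e-9)
})

test_that("standardization preserves the missing mask and rejects degenerates", {
  fp <- mk_fp(c(1, NA, 3, 5))
  out <- standardize_fingerprints(fp)
  expect_true(is.na(out$value[2]))
  expect_equal(sum(is.na(out$value)), 1)
  expect_error(standardize_fingerprints(mk_fp(c(2, 2, 2))), "variance")
  expect_error(standardize_fingerprints(mk_fp(c(2, NA, NA))), "fewer than 2")
})

test_that("comparison reports r2, mae, slope and intercept", {
  set.seed(10)
  obs <- mk_fp(rnorm(8))
  ident <- compare_fingerprints(obs, obs)
  expect_equal(ident$r2, 1)
  expect_equal(ident$mae, 0)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  # standardized pair: intercept 0, slope = Pearson r
  theo <- mk_fp(obs$value * 0.8 + rnorm(8, sd = 0.3))
  so <- standardize_fingerprints(obs)
  st <- standardize_fingerprints(theo)
  cmp <- compare_fingerprints(so, st)
  r <- cor(so$value, st$value)
  expect_equal(cmp$intercept, 0, tolerance = 1e-12)
  expect_equal(cmp$slope, r, tolerance = 1e-12)
  expect_equal(cmp$r2, r^2, tolerance = 1e-12)
  expect_true(cmp$standardized)

  # standardizing removes a pure additive offset, so the MAE cannot grow
  shifted <- mk_fp(obs$value + 1.2)
  raw_mae <- compare_fingerprints(shifted, obs)$mae
  std_mae <- compare_fingerprints(standardize_fingerprints(shifted),
                                  standardize_fingerprints(obs))$mae
  expect_lte(std_mae, raw_mae)
  expect_equal(std_mae, 0, tolerance = 1e-12)
})

test_that("comparison needs at least 3 common solvents", {
  obs <- mk_fp(c(1, 2, NA, NA, 5))
  theo <- mk_fp(c(1.1, NA, 3, 4, 5.2))
  expect_message(cmp <- compare_fingerprints(obs, theo), "dropped")
  expect_equal(nrow(cmp), 0)
})

test_that("cross-platform selection is inclusive at the threshold", {
  cmps <- tibble::tibble(compound_id = c("A", "B", "C"),
                         r2 = c(0.80, 0.79, 0.95))
  expect_equal(cross_platform_select(cmps), c("A", "C"))
  # identical platforms retain everything
  ident <- tibble::tibble(compound_id = c("A", "B"), r2 = c(1, 1))
  expect_equal(cross_platform_select(ident), c("A", "B"))
})

test_that("distribution-ratio inference is additive and involutive", {
  expect_equal(infer_distribution_ratio(2, 3, 1.5), 0.5)
  expect_equal(infer_distribution_ratio(3, 2, 1.5), 2.5)
  # un-ionized anchor (log D = log K) returns the target log K
  expect_equal(infer_distribution_ratio(2.2, 3.3, 3.3), 2.2)
  # inferring A -> B then B -> A returns the original value
  set.seed(12)
  ka <- rnorm(20); kb <- rnorm(20); da <- ka + log10(runif(20, 0.05, 1))
  db_ <- infer_distribution_ratio(kb, ka, da)
  expect_equal(infer_distribution_ratio(ka, kb, db_), da, tolerance = 1e-12)
})

test_that("ionized compounds: standardized D equals standardized K", {
  panel <- clean_panel()
  ion <- panel$fingerprints |>
    dplyr::filter(f_u < 1) |>
    dplyr::pull(compound_id) |>
    unique()
  expect_gt(length(ion), 0)
  d_std <- standardize_fingerprints(truth_fp(panel, ion,
                                             value_col = "log_d"))
  k_std <- standardize_fingerprints(truth_fp(panel, ion,
                                             value_col = "log_k"))
  expect_equal(d_std$value, k_std$value, tolerance = 1e-12)
})
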