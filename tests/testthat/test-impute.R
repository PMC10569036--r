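test_that("read-across OLS recovers a planted linear law", {
  set.seed(5)
  db <- tibble::tibble(logK_a = rnorm(60), logK_b = rnorm(60),
                       logK_c = rnorm(60))
  db$logK_t <- 2 * db$logK_a - db$logK_b + 0.5 * db$logK_c + 1
  m <- fit_readacross(db, "t", c("a", "b", "c"))
  expect_equal(unname(m$coefficients),
               c(1, 2, -1, 0.5), tolerance = 1e-8)
  expect_equal(m$n_train, 60)

  # constant target: zero weights, intercept = the constant
  db$logK_t <- 3.7
  m2 <- fit_readacross(db, "t", c("a", "b", "c"))
  expect_equal(unname(m2$coefficients), c(3.7, 0, 0, 0), tolerance = 1e-8)

  # too few complete cases
  expect_error(fit_readacross(db[1:3, ], "t", c("a", "b", "c")), "4")
  # rank-deficient design raises a typed condition
  db$logK_b <- db$logK_a
  expect_error(fit_readacross(db, "t", c("a", "b", "c")),
               class = "partprint_rank_deficient")
})

test_that("imputation is exact on a rank-latent database", {
  panel <- cached_panel("imp", sim_config(n_compounds = 300, seed = 7))
  truth <- truth_fp(panel)
  ids <- sprintf("CMP%04d", 1:15)
  fp <- truth_fp(panel, ids)
  hidden <- c("hexane", "toluene", "octanol")
  fp$value[fp$solvent %in% hidden] <- NA
  imp <- impute_fingerprints(fp, panel$reference_db, n_iter = 25, seed = 1)
  chk <- dplyr::inner_join(
    dplyr::filter(imp, imputed),
    dplyr::select(truth, compound_id, solvent, true = value),
    by = c("compound_id", "solvent")
  )
  expect_equal(nrow(chk), length(ids) * length(hidden))
  expect_lt(max(abs(chk$value - chk$true)), 1e-6)
  expect_true(all(imp$imputed[is.na(fp$value)]))
})

test_that("imputation is a seeded, deterministic identity on complete data", {
  panel <- cached_panel("imp", sim_config(n_compounds = 300, seed = 7))
  fp <- truth_fp(panel, sprintf("CMP%04d", 1:5))
  expect_identical(impute_fingerprints(fp, panel$reference_db, seed = 2), fp)

  fp$value[fp$solvent == "octane"] <- NA
  a <- impute_fingerprints(fp, panel$reference_db, n_iter = 15, seed = 42)
  b <- impute_fingerprints(fp, panel$reference_db, n_iter = 15, seed = 42)
  expect_identical(a, b)
})

test_that("compounds with fewer than 3 observed solvents are left alone", {
  panel <- cached_panel("imp", sim_config(n_compounds = 300, seed = 7))
  fp <- truth_fp(panel, "CMP0001")
  fp$value[3:10] <- NA # only 2 observed
  expect_warning(
    out <- impute_fingerprints(fp, panel$reference_db, n_iter = 5, seed = 1),
    "fewer than 3"
  )
  expect_identical(out$value, fp$value)
})

test_that("across-seed spread of imputed values shrinks with n_iter", {
  panel <- cached_panel("imp", sim_config(n_compounds = 300, seed = 7))
  set.seed(31)
  db <- panel$reference_db
  noisy <- dplyr::mutate(db, dplyr::across(dplyr::starts_with("logK_"),
                                           ~ .x + rnorm(dplyr::n(), sd = 0.4)))
  fp <- truth_fp(panel, "CMP0002")
  fp$value[fp$solvent == "undecane"] <- NA
  est <- function(n_iter, seed) {
    out <- impute_fingerprints(fp, noisy, n_iter = n_iter, seed = seed)
    out$value[out$solvent == "undecane"]
  }
  small <- vapply(1:12, function(s) est(10, s), numeric(1))
  large <- vapply(1:12, function(s) est(1000, 100 + s), numeric(1))
  expect_lt(sd(large), sd(small) / 2) # ~ sqrt(100)-fold fewer would give /10
})
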