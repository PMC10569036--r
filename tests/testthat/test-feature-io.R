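test_that("feature table round-trips through CSV at full precision", {
  panel <- clean_panel()
  dir <- withr::local_tempdir()
  fpath <- file.path(dir, "features.csv")
  mpath <- file.path(dir, "manifest.csv")
  write_feature_table(panel$features, fpath, mpath)
  back <- read_feature_table(fpath, mpath)

  orig <- dplyr::arrange(panel$features, feature_id, sample_id)
  back <- dplyr::arrange(back, feature_id, sample_id)[names(orig)]
  # CSV serialization keeps 15 significant digits
  expect_equal(back$area, unname(orig$area), tolerance = 1e-12)
  expect_equal(back$role, orig$role)
  expect_equal(as.integer(back$replicate), orig$replicate)
  expect_equal(nrow(back), nrow(orig))
})

test_that("reader validates manifest coverage and roles", {
  panel <- clean_panel()
  dir <- withr::local_tempdir()
  fpath <- file.path(dir, "features.csv")
  mpath <- file.path(dir, "manifest.csv")
  write_feature_table(panel$features, fpath, mpath)

  manifest <- readr::read_csv(mpath, show_col_types = FALSE)
  dropped <- manifest$sample_id[1]
  readr::write_csv(manifest[-1, ], mpath)
  expect_warning(read_feature_table(fpath, mpath), dropped)

  # a manifest sample missing from the table names the column
  manifest2 <- dplyr::bind_rows(
    manifest,
    dplyr::mutate(manifest[1, ], sample_id = "GHOST_SAMPLE")
  )
  readr::write_csv(manifest2, mpath)
  expect_error(read_feature_table(fpath, mpath), "GHOST_SAMPLE")

  readr::write_csv(dplyr::mutate(manifest, role = "mystery"), mpath)
  expect_error(read_feature_table(fpath, mpath), "role")

  # missing a required feature column is a format error
  feats <- readr::read_csv(fpath, show_col_types = FALSE)
  readr::write_csv(dplyr::select(feats, -mz), fpath)
  readr::write_csv(manifest, mpath)
  expect_error(read_feature_table(fpath, mpath), "mz")
})

test_that("mass matching applies the ppm window on the theoretical mass", {
  db <- tibble::tibble(compound_id = "A", monoisotopic_mass = 300)
  f10 <- tibble::tibble(feature_id = "F1", mz = 300.003)
  hit <- match_features(f10, db, ppm_tol = 10, adduct = "none")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ppm_error, 10, tolerance = 1e-9)
  expect_equal(nrow(match_features(f10, db, ppm_tol = 5, adduct = "none")), 0)

  # adduct correction: [M+H]+ features sit one proton above the neutral mass
  fadd <- tibble::tibble(feature_id = "F1", mz = 300 + 1.007276)
  hit2 <- match_features(fadd, db, ppm_tol = 10, adduct = "[M+H]+")
  expect_equal(hit2$ppm_error, 0, tolerance = 1e-6)
})

test_that("matching is sign-symmetric and monotone in the tolerance", {
  db <- tibble::tibble(compound_id = c("A", "B"),
                       monoisotopic_mass = c(250, 400))
  set.seed(42)
  for (ppm in c(2, 7, 10)) {
    up <- tibble::tibble(feature_id = "U", mz = 250 * (1 + ppm * 1e-6))
    dn <- tibble::tibble(feature_id = "D", mz = 250 * (1 - ppm * 1e-6))
    expect_equal(nrow(match_features(up, db, ppm, adduct = "none")),
                 nrow(match_features(dn, db, ppm, adduct = "none")))
  }
  feats <- tibble::tibble(feature_id = sprintf("F%02d", 1:20),
                          mz = 250 * (1 + runif(20, -2e-5, 2e-5)))
  wide <- match_features(feats, db, ppm_tol = 15, adduct = "none")
  narrow <- match_features(feats, db, ppm_tol = 6, adduct = "none")
  expect_true(all(narrow$feature_id %in% wide$feature_id))
  expect_lte(nrow(narrow), nrow(wide))
  expect_warning(
    match_features(feats, db[0, ], ppm_tol = 10, adduct = "none"), "empty"
  )
})

test_that("blank filter keeps features at or above the blank ratio", {
  mk <- function(sample_area, blank_area) {
    tibble::tibble(
      feature_id = "F1",
      sample_id = c("w1", "b1", "b2"),
      area = c(sample_area, blank_area, blank_area),
      role = c("water_control", "blank", "blank")
    )
  }
  expect_equal(blank_filter(mk(130, 100), 1.3), "F1") # inclusive boundary
  expect_equal(blank_filter(mk(129, 100), 1.3), character(0))
  expect_equal(blank_filter(mk(1, 0), 1.3), "F1")     # zero blank retains
  expect_error(blank_filter(dplyr::filter(mk(130, 100), role != "blank")),
               "blank")
  # ratio 1 keeps everything at or above the mean blank area
  expect_equal(blank_filter(mk(100, 100), 1), "F1")
})

test_that("reference database reader validates the contract", {
  panel <- clean_panel()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "db.csv")
  write_reference_db(panel$reference_db, path)
  db <- read_reference_db(path, panel = panel$config$solvents)
  expect_equal(nrow(db), nrow(panel$reference_db))
  expect_error(read_reference_db(path, panel = c("octanol")), "panel")

  bad <- dplyr::mutate(panel$reference_db, monoisotopic_mass = -1)
  write_reference_db(bad, path)
  expect_error(read_reference_db(path), "mass")
})
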