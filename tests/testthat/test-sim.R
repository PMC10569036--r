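test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(n_compounds = 15, seed = 99)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$fingerprints, b$fingerprints)
  expect_identical(a$features, b$features)
  expect_identical(a$isomers, b$isomers)
  c_ <- simulate_panel(sim_config(n_compounds = 15, seed = 100))
  expect_false(identical(a$features$area, c_$features$area))
})

test_that("simulated compounds have valid counts, formulas and masses", {
  panel <- clean_panel()
  comp <- panel$compounds
  expect_equal(nrow(comp), 30)
  frag <- as.matrix(comp[paste0("frag_", panel$config$fragments)])
  expect_true(all(frag >= 0 & frag <= 4))
  expect_true(all(frag == round(frag)))
  expect_true(all(comp$monoisotopic_mass > 0))
  expect_equal(comp$monoisotopic_mass, formula_mass(comp$formula))
  expect_false(anyDuplicated(comp$formula) > 0)
})

test_that("any 3 solvents determine a 4th exactly (rank-latent structure)", {
  panel <- clean_panel()
  wide <- tidyr::pivot_wider(
    dplyr::select(panel$fingerprints, compound_id, solvent, log_k),
    names_from = solvent, values_from = log_k
  )
  fit <- lm(octanol ~ hexane + toluene + chloroform, data = wide)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  fit2 <- lm(undecane ~ octane + dichloromethane + cyclohexane, data = wide)
  expect_lt(max(abs(residuals(fit2))), 1e-9)
})

test_that("ionization produces a solvent-independent offset", {
  panel <- clean_panel()
  fp <- panel$fingerprints
  neutral <- dplyr::filter(fp, f_u == 1)
  expect_equal(neutral$log_d, neutral$log_k)
  ionized <- dplyr::filter(fp, f_u < 1)
  expect_gt(nrow(ionized), 0)
  offsets <- ionized |>
    dplyr::group_by(compound_id) |>
    dplyr::summarise(spread = diff(range(log_d - log_k)),
                     off = mean(log_d - log_k), fu = f_u[1])
  expect_lt(max(offsets$spread), 1e-12)
  expect_equal(offsets$off, log10(offsets$fu), tolerance = 1e-12)
})

test_that("rendered areas satisfy mass balance in the clean linear case", {
  panel <- clean_panel()
  cfg <- panel$config
  feats <- panel$features
  expect_true(all(feats$area >= 0))
  expect_true(all(feats$area[feats$role == "blank"] > 0))

  m <- match_features(feats, panel$reference_db, ppm_tol = 1,
                      adduct = "[M+H]+")
  joined <- feats |>
    dplyr::filter(role %in% c("partition", "water_control")) |>
    dplyr::inner_join(m, by = "feature_id") |>
    dplyr::inner_join(panel$fingerprints, by = c("compound_id", "solvent")) |>
    dplyr::inner_join(panel$rrf, by = "compound_id")
  wide <- joined |>
    dplyr::group_by(compound_id, solvent, replicate, v_w, v_s, log_d, rrf) |>
    dplyr::summarise(
      a_w = mean(area[role == "partition"]),
      a_t = mean(area[role == "water_control"]), .groups = "drop"
    )
  d <- 10^wide$log_d
  # solvent-phase amount of a unit spike after equilibration
  n_solvent <- d * wide$v_s / (wide$v_w + d * wide$v_s)
  lhs <- (wide$a_t - wide$a_w) * wide$v_w / (wide$rrf * cfg$area_scale)
  expect_equal(unname(lhs), n_solvent, tolerance = 1e-10)
})

test_that("the saturating response is monotone and bounded", {
  panel_lin <- clean_panel()
  a <- seq(0, 10, by = 0.1)
  out <- partprint:::sigmoid_response(a, level = 2, steepness = 2)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out <= 4 + 1e-12)) # asymptote at twice the onset level
  expect_equal(partprint:::sigmoid_response(2, 2, 2), 2) # identity point
  expect_equal(out[1], 0)

  # dropout zeroes some signal measurements
  cfg_d <- sim_config(n_compounds = 10, dropout_prob = 0.3, seed = 5)
  feats_d <- simulate_panel(cfg_d)$features
  signal <- dplyr::filter(feats_d, role != "blank")
  expect_gt(mean(signal$area == 0), 0.1)
})
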