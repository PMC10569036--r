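# Shared fixtures: small simulated panels, built once per test run.

panel_cache <- new.env(parent = emptyenv())

cached_panel <- function(name, cfg) {
  if (is.null(panel_cache[[name]])) {
    panel_cache[[name]] <- simulate_panel(cfg)
  }
  panel_cache[[name]]
}

# Clean panel: no area noise, linear response, no dropout.
clean_panel <- function() {
  cached_panel("clean", sim_config(n_compounds = 30, noise_sd_area = 0,
                                   seed = 3))
}

# Noisy panel at the default 5% relative area noise.
noisy_panel <- function() {
  cached_panel("noisy", sim_config(n_compounds = 60, noise_sd_area = 0.05,
                                   seed = 11))
}

# Truth as a fingerprint tibble (neutral log K).
truth_fp <- function(panel, ids = NULL, value_col = "log_k") {
  fp <- panel$fingerprints |>
    dplyr::select("compound_id", "solvent",
                  value = dplyr::all_of(value_col)) |>
    dplyr::mutate(imputed = FALSE, standardized = FALSE)
  if (!is.null(ids)) fp <- dplyr::filter(fp, .data$compound_id %in% ids)
  fp
}

# Run match + blank filter + fingerprint assembly on a panel.
panel_fingerprints <- function(panel, ...) {
  feats <- panel$features
  m <- match_features(feats, panel$reference_db, ppm_tol = 10,
                      adduct = "[M+H]+")
  m <- dplyr::filter(m, .data$feature_id %in% blank_filter(feats))
  suppressWarnings(
    build_fingerprints(feats, m, panel = panel$config$solvents, ...)
  )
}

# Standardized-fingerprint modelling table built from a panel's reference
# database (theoretical fingerprints + priors + true fragment counts).
panel_model_data <- function(panel, fp_noise_sd = 0, noise_seed = 1) {
  db <- panel$reference_db
  fp <- db |>
    dplyr::select("compound_id", dplyr::starts_with("logK_")) |>
    tidyr::pivot_longer(dplyr::starts_with("logK_"), names_to = "solvent",
                        values_to = "value", names_prefix = "logK_") |>
    dplyr::mutate(imputed = FALSE, standardized = FALSE)
  if (fp_noise_sd > 0) {
    set.seed(noise_seed)
    fp$value <- fp$value + rnorm(nrow(fp), sd = fp_noise_sd)
  }
  prepare_model_data(standardize_fingerprints(fp), db,
                     priors = fragment_priors(panel$isomers),
                     panel = panel$config$solvents)
}
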