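#' Configuration for the synthetic partitioning panel
#'
#' Builds the configuration object consumed by [simulate_panel()] and its
#' stage functions. The simulator emulates a shake-flask solvent-water
#' partitioning campaign read out by LC-MS: compounds with integer
#' substructure (fragment) counts, theoretical log K_SW fingerprints generated
#' from a small number of latent solute descriptors (an LSER-like linear
#' structure), per-compound ionization offsets (log D = log K + log10 f_u),
#' per-compound response factors, lognormal peak-area noise, blank signal,
#' detection dropout, and an optional saturating detector response that mimics
#' a narrow intrascan dynamic range.
#'
#' @param n_compounds Number of compounds in the panel.
#' @param solvents Character vector naming the solvent panel.
#' @param fragments Character vector naming the substructure catalog.
#' @param latent_dim Number of latent solute descriptors. The default 3 makes
#'   every fingerprint exactly reconstructible from any 3 generic solvents,
#'   which is the oracle used to test read-across imputation.
#' @param latent_noise_sd SD of compound-level latent noise (adds diversity
#'   beyond what fragment counts explain; does not break the rank-latent
#'   structure of the fingerprints).
#' @param noise_sd_area Relative (lognormal) SD of measured peak areas.
#' @param ionized_fraction Fraction of compounds that are ionized at the
#'   working pH.
#' @param f_u_range Range of the un-ionized fraction f_u for ionized
#'   compounds (drawn uniformly).
#' @param response Detector response: `"linear"` or `"sigmoid"` (saturating).
#' @param saturation_quantile For the sigmoid response, the quantile of the
#'   noise-free area distribution at which saturation sets in.
#' @param steepness Shape parameter of the sigmoid response (> 1 also
#'   suppresses the low end of the curve).
#' @param dropout_prob Probability that a compound goes undetected (area 0)
#'   in any one measurement.
#' @param blank_level Blank signal level relative to the median water-control
#'   area.
#' @param volumes Data frame with columns `replicate`, `v_w`, `v_s` (mL)
#'   giving the water and solvent volumes of each replicate experiment.
#'   Defaults to the 1:1, 2:1 and 0.5:1 solvent:water ratios of a standard
#'   OECD-style shake-flask design.
#' @param n_injections Number of injection duplicates per sample.
#' @param isomers_per_formula Average number of isomer records per formula in
#'   the simulated isomer metadata (see [simulate_isomers()]); makes fragment
#'   priors informative without simply restating each compound's counts.
#' @param ionization_mode `"positive"` or `"negative"`; sets the adduct used
#'   to render observed m/z.
#' @param area_scale Multiplier converting simulated concentrations to
#'   instrument-like peak areas.
#' @param seed Integer seed; a fixed seed makes the whole panel deterministic.
#'
#' @return A list of class `sim_config`.
#' @export
#'
#' @examples
#' cfg <- sim_config(n_compounds = 20, seed = 1)
#' panel <- simulate_panel(cfg)
#' dplyr::glimpse(panel$compounds)
sim_config <- function(n_compounds = 200,
                       solvents = default_solvents(),
                       fragments = default_fragments(),
                       latent_dim = 3,
                       latent_noise_sd = 0.3,
                       noise_sd_area = 0.05,
                       ionized_fraction = 0.3,
                       f_u_range = c(0.1, 1),
                       response = c("linear", "sigmoid"),
                       saturation_quantile = 0.6,
                       steepness = 2,
                       dropout_prob = 0,
                       blank_level = 0.001,
                       volumes = default_volumes(),
                       n_injections = 2,
                       isomers_per_formula = 3,
                       ionization_mode = c("positive", "negative"),
                       area_scale = 1e6,
                       seed = 1L) {
  response <- match.arg(response)
  ionization_mode <- match.arg(ionization_mode)
  stopifnot(
    n_compounds >= 1, latent_dim >= 3,
    ionized_fraction >= 0, ionized_fraction <= 1,
    dropout_prob >= 0, dropout_prob <= 1,
    all(f_u_range > 0), all(f_u_range <= 1),
    saturation_quantile > 0, saturation_quantile < 1,
    noise_sd_area >= 0, blank_level >= 0,
    all(c("replicate", "v_w", "v_s") %in% names(volumes)),
    all(volumes$v_w > 0), all(volumes$v_s > 0),
    n_injections >= 1
  )
  structure(
    list(
      n_compounds = as.integer(n_compounds), solvents = solvents,
      fragments = fragments, latent_dim = as.integer(latent_dim),
      latent_noise_sd = latent_noise_sd, noise_sd_area = noise_sd_area,
      ionized_fraction = ionized_fraction, f_u_range = f_u_range,
      response = response, saturation_quantile = saturation_quantile,
      steepness = steepness, dropout_prob = dropout_prob,
      blank_level = blank_level, volumes = tibble::as_tibble(volumes),
      n_injections = as.integer(n_injections),
      isomers_per_formula = isomers_per_formula,
      ionization_mode = ionization_mode, area_scale = area_scale,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default substructure catalog for simulation
#'
#' @return Character vector of fragment (substructure) names.
#' @export
default_fragments <- function() {
  c("benzene", "phenol", "alcohol", "ether", "ester", "amine_primary",
    "amine_secondary", "amide", "halogen", "ketone", "carboxylic_acid",
    "nitro")
}

#' Default replicate volume design
#'
#' Solvent:water volume ratios 1:1, 2:1 and 0.5:1 across the three replicate
#' experiments, with 1 mL of water each.
#'
#' @return Tibble with columns `replicate`, `v_w`, `v_s`.
#' @export
default_volumes <- function() {
  tibble::tibble(replicate = 1:3, v_w = c(1, 1, 1), v_s = c(1, 2, 0.5))
}

#' Simulate compounds with fragment counts and formulas
#'
#' Draws compounds with small non-negative integer substructure counts and a
#' unique molecular formula each (a study mixture is designed to be
#' resolvable by monoisotopic mass; isomer families are modelled separately
#' by [simulate_isomers()]). Each compound also receives a
#' literature-popularity score (`data_sources`) used by the fragment-prior
#' module.
#'
#' @param cfg A [sim_config()].
#'
#' @return Tibble with columns `compound_id`, `formula`, `monoisotopic_mass`,
#'   `smiles` (a synthetic placeholder token), `data_sources`, and one
#'   `frag_<name>` column per catalog fragment (non-negative integers).
#' @export
simulate_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  nf <- length(cfg$fragments)

  # Per-compound fragment propensities and counts.
  lambda <- matrix(rgamma2(n * nf, shape = 0.5, rate = 1.2), nrow = n)
  counts <- matrix(0L, nrow = n, ncol = nf,
                   dimnames = list(NULL, paste0("frag_", cfg$fragments)))
  for (i in seq_len(n)) {
    counts[i, ] <- pmin(rpois(nf, lambda[i, ]), 4L)
  }

  # One unique formula per compound (the study mixture is resolvable by
  # monoisotopic mass; isomer families live in the isomer metadata, see
  # simulate_isomers()). Plausible CHNO(S,Cl) organics; duplicates redrawn.
  formulas <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    for (attempt in 1:1000) {
      c_n <- 6L + rpois(1, 6)
      h_n <- c_n + rpois(1, 4)
      el <- c(C = c_n, H = h_n, N = rpois(1, 1), O = rpois(1, 2),
              S = rbinom(1, 1, 0.15), Cl = rpois(1, 0.4))
      f <- format_formula(el)
      if (!f %in% seen) break
    }
    formulas[i] <- f
    seen <- c(seen, f)
  }

  tibble::tibble(
    compound_id = sprintf("CMP%04d", seq_len(n)),
    formula = formulas,
    monoisotopic_mass = formula_mass(formulas),
    smiles = sprintf("SYN[%04d]", seq_len(n)),
    data_sources = rpois(n, 8) * rbinom(n, 1, 0.9)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(counts))
}

#' Simulate isomer metadata for fragment priors
#'
#' Emulates a structure-database search: for each compound's molecular
#' formula it returns the compound's own structure plus additional
#' hypothetical isomers (fragment counts perturbed around the compound's),
#' each with a literature-popularity `data_sources` score. The compound's
#' own structure is usually, but not always, the best documented, so the
#' resulting priors are informative without simply restating the truth.
#'
#' @param compounds Output of [simulate_compounds()].
#' @param cfg A [sim_config()]; `isomers_per_formula` sets the average
#'   number of isomers per formula.
#'
#' @return Tibble with columns `formula`, `smiles`, `data_sources` and
#'   `frag_<name>` counts, one row per isomer.
#' @export
simulate_isomers <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  frag_cols <- paste0("frag_", cfg$fragments)
  extra_mean <- max(cfg$isomers_per_formula - 1, 0)
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    own <- compounds[i, c("formula", "smiles", "data_sources", frag_cols)]
    n_extra <- rpois(1, extra_mean)
    if (n_extra == 0) return(own)
    base <- as.integer(compounds[i, frag_cols])
    extras <- lapply(seq_len(n_extra), function(j) {
      counts <- pmax(base + sample(c(-1L, 0L, 1L), length(base),
                                   replace = TRUE,
                                   prob = c(0.25, 0.5, 0.25)), 0L)
      out <- tibble::tibble(
        formula = own$formula,
        smiles = sprintf("SYN[%s-iso%d]", compounds$compound_id[i], j),
        data_sources = rpois(1, max(1, compounds$data_sources[i] / 2))
      )
      out[frag_cols] <- as.list(counts)
      out
    })
    dplyr::bind_rows(own, extras)
  })
  dplyr::bind_rows(rows)
}

# rgamma with a stable name to keep the seed stream explicit in one place
rgamma2 <- function(n, shape, rate) stats::rgamma(n, shape = shape, rate = rate)

#' Simulate true partition fingerprints
#'
#' Generates latent solute descriptors as a linear function of fragment
#' counts plus compound-level noise, then maps them linearly (with a
#' solvent-specific loading and intercept) to log K_SW for every solvent.
#' Because the solvent maps act on `latent_dim` shared latents, any
#' `latent_dim` generic solvents determine all others exactly; this is the
#' structure that read-across imputation exploits. Ionized compounds receive
#' an un-ionized fraction f_u and log D = log K + log10(f_u), the same offset
#' in every solvent.
#'
#' @param compounds Output of [simulate_compounds()].
#' @param cfg A [sim_config()].
#'
#' @return Tibble with columns `compound_id`, `solvent`, `log_k`, `log_d`,
#'   `f_u`.
#' @export
simulate_fingerprints <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(compounds)
  nf <- length(cfg$fragments)
  d <- cfg$latent_dim

  frag <- as.matrix(compounds[paste0("frag_", cfg$fragments)])
  b_map <- matrix(rnorm(nf * d, sd = 0.25), nrow = nf)
  latents <- frag %*% b_map +
    matrix(rnorm(n * d, sd = cfg$latent_noise_sd), nrow = n)

  loadings <- matrix(rnorm(length(cfg$solvents) * d, sd = 0.8), ncol = d,
                     dimnames = list(cfg$solvents, NULL))
  intercepts <- rnorm(length(cfg$solvents), mean = 2, sd = 0.5)
  log_k <- latents %*% t(loadings) +
    matrix(intercepts, n, length(cfg$solvents), byrow = TRUE)

  ionized <- runif(n) < cfg$ionized_fraction
  f_u <- ifelse(ionized, runif(n, cfg$f_u_range[1], cfg$f_u_range[2]), 1)

  tibble::tibble(
    compound_id = rep(compounds$compound_id, each = length(cfg$solvents)),
    solvent = rep(cfg$solvents, times = n),
    log_k = as.numeric(t(log_k)),
    f_u = rep(f_u, each = length(cfg$solvents))
  ) |>
    dplyr::mutate(log_d = .data$log_k + log10(.data$f_u)) |>
    dplyr::select("compound_id", "solvent", "log_k", "log_d", "f_u")
}

# Saturating detector response: a log-logistic calibration curve that is
# approximately proportional around `level` and compresses both tails for
# steepness > 1. Identity at a = level; asymptote at 2 * level.
sigmoid_response <- function(area, level, steepness) {
  out <- 2 * level / (1 + (level / pmax(area, .Machine$double.xmin))^steepness)
  out[area <= 0] <- 0
  out
}

#' Render a simulated feature table
#'
#' Converts ground-truth fingerprints into an aligned LC-MS feature table by
#' mass balance: the water-control area reflects the spiked aqueous
#' concentration before equilibration and the partition-sample area the
#' aqueous concentration after equilibration against the organic phase, both
#' scaled by a per-compound response factor (which therefore cancels in the
#' area ratio). Lognormal noise, the configured response curve, detection
#' dropout, and blank samples are applied on top. Water controls, partition
#' samples, blanks, replicates and injection duplicates are all emitted.
#'
#' @param truth List with elements `compounds` and `fingerprints` (see
#'   [simulate_compounds()], [simulate_fingerprints()]).
#' @param cfg A [sim_config()].
#'
#' @return List with `features` (long tibble: `feature_id`, `mz`, `rt`,
#'   `sample_id`, `area`, plus manifest columns `role`, `solvent`,
#'   `replicate`, `injection`, `v_w`, `v_s`) and `rrf` (per-compound response
#'   factors).
#' @export
render_feature_table <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  compounds <- truth$compounds
  fp <- truth$fingerprints
  n <- nrow(compounds)

  rrf <- 10^runif(n, -0.5, 0.5) # log-uniform over one decade
  names(rrf) <- compounds$compound_id

  adduct <- if (cfg$ionization_mode == "positive") PROTON_MASS else -PROTON_MASS
  feat <- tibble::tibble(
    feature_id = sprintf("F%04d", seq_len(n)),
    compound_id = compounds$compound_id,
    mz = compounds$monoisotopic_mass + adduct,
    rt = round(runif(n, 1, 15), 3)
  )

  grid <- tidyr::expand_grid(
    solvent = cfg$solvents,
    cfg$volumes,
    role = c("partition", "water_control"),
    injection = seq_len(cfg$n_injections)
  )
  blanks <- tidyr::expand_grid(
    solvent = NA_character_,
    replicate = cfg$volumes$replicate,
    v_w = NA_real_, v_s = NA_real_,
    role = "blank",
    injection = seq_len(cfg$n_injections)
  )
  manifest <- dplyr::bind_rows(grid, blanks) |>
    dplyr::mutate(sample_id = paste0(
      substr(.data$role, 1, 1), "_",
      dplyr::coalesce(.data$solvent, "blank"),
      "_r", .data$replicate, "_i", .data$injection
    )) |>
    dplyr::select("sample_id", "role", "solvent", "replicate", "injection",
                  "v_w", "v_s")

  rows <- tidyr::expand_grid(feat, manifest) |>
    dplyr::left_join(fp, by = c("compound_id", "solvent"))

  d_eff <- 10^rows$log_d
  clean <- dplyr::case_when(
    rows$role == "water_control" ~
      rrf[rows$compound_id] * (1 / rows$v_w) * cfg$area_scale,
    rows$role == "partition" ~
      rrf[rows$compound_id] * (1 / (rows$v_w + d_eff * rows$v_s)) *
        cfg$area_scale,
    TRUE ~ 0
  )

  blank_base <- cfg$blank_level * median(clean[rows$role == "water_control"])
  clean[rows$role == "blank"] <- blank_base

  noise <- if (cfg$noise_sd_area > 0) {
    exp(rnorm(length(clean), sd = cfg$noise_sd_area))
  } else rep(1, length(clean))
  area <- clean * noise

  if (cfg$response == "sigmoid") {
    signal <- rows$role != "blank"
    level <- quantile(clean[signal], cfg$saturation_quantile, names = FALSE)
    area[signal] <- sigmoid_response(area[signal], level, cfg$steepness)
  }

  if (cfg$dropout_prob > 0) {
    drop <- runif(length(area)) < cfg$dropout_prob & rows$role != "blank"
    area[drop] <- 0
  }

  features <- rows |>
    dplyr::mutate(area = area) |>
    dplyr::select("feature_id", "mz", "rt", "sample_id", "area", "role",
                  "solvent", "replicate", "injection", "v_w", "v_s")

  list(features = features,
       rrf = tibble::tibble(compound_id = compounds$compound_id, rrf = rrf))
}

#' Simulate a complete synthetic panel
#'
#' Runs [simulate_compounds()], [simulate_fingerprints()] and
#' [render_feature_table()] and assembles the reference-database view
#' (theoretical log K_SW plus fragment counts, as a curated property database
#' would supply them).
#'
#' @param cfg A [sim_config()].
#'
#' @return List of class `sim_panel` with elements `config`, `compounds`,
#'   `fingerprints` (ground truth), `features` (rendered feature table, long
#'   format), `rrf`, `reference_db` (wide tibble with `logK_<solvent>` and
#'   `frag_<name>` columns), and `isomers` (metadata for fragment priors,
#'   see [simulate_isomers()]).
#' @export
#'
#' @examples
#' panel <- simulate_panel(sim_config(n_compounds = 10, seed = 42))
#' names(panel)
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  compounds <- simulate_compounds(cfg)
  fingerprints <- simulate_fingerprints(compounds, cfg)
  rendered <- render_feature_table(
    list(compounds = compounds, fingerprints = fingerprints), cfg
  )

  log_k_wide <- fingerprints |>
    dplyr::select("compound_id", "solvent", "log_k") |>
    tidyr::pivot_wider(names_from = "solvent", values_from = "log_k",
                       names_prefix = "logK_")
  reference_db <- compounds |>
    dplyr::left_join(log_k_wide, by = "compound_id") |>
    dplyr::select("compound_id", "formula", "monoisotopic_mass", "smiles",
                  "data_sources", dplyr::starts_with("logK_"),
                  dplyr::starts_with("frag_"))

  structure(
    list(config = cfg, compounds = compounds, fingerprints = fingerprints,
         features = rendered$features, rrf = rendered$rrf,
         reference_db = reference_db,
         isomers = simulate_isomers(compounds, cfg)),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel>", x$config$n_compounds, "compounds x",
      length(x$config$solvents), "solvents;",
      length(x$config$fragments), "fragments; response:",
      x$config$response, "\n")
  invisible(x)
}
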