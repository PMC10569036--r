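#' Run the full measurement-to-structure pipeline
#'
#' Executes the configured stages end to end: read the feature table and
#' manifest, match features to reference compounds by mass, blank-filter,
#' compute log K_SW fingerprints, impute missing panel entries, standardize,
#' compare against the theoretical fingerprints of the reference database,
#' derive fragment priors, and either train the fragment-count network or
#' predict with a saved one. Every stage writes its CSV into the output
#' directory along with a JSON provenance record (package version, seeds,
#' configuration hash) sufficient to reproduce the run.
#'
#' The configuration is a named list (or path to a YAML file) with at least:
#' \preformatted{
#' paths:
#'   features:     feature-table CSV
#'   manifest:     manifest CSV
#'   reference_db: reference database CSV
#'   isomers:      isomer metadata CSV (optional; priors fall back to the
#'                 reference database's own data_sources and frag_* columns)
#'   model_dir:    saved model directory (required when model.train: false)
#'   out_dir:      output directory
#' platform:       "qtof" (10 ppm) or "orbitrap" (5 ppm)
#' adduct:         "[M+H]+", "[M-H]-", or "none"
#' blank_ratio:    1.3
#' volume_correction: true
#' imputation:     {n_iter: 100, seed: 1}
#' model:          {train: true, epochs: 200, cv_folds: 5, batch_size: 32,
#'                  hidden: 500, n_relu: 10, dropout: 0.2, seed: 1}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#'
#' @return Invisibly, a list with the stage outputs (`matches`,
#'   `fingerprints`, `imputed`, `standardized`, `comparisons`, `priors`,
#'   `model` and/or `predictions`, `evaluation`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(out_dir = cfg$paths$out_dir)
  emit <- function(name, obj) {
    readr::write_csv(obj, file.path(cfg$paths$out_dir,
                                    paste0(name, ".csv")),
                     progress = FALSE)
    obj
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  features <- stage("read", read_feature_table(cfg$paths$features,
                                               cfg$paths$manifest))
  db <- stage("read", read_reference_db(cfg$paths$reference_db))

  ppm_tol <- if (cfg$platform == "orbitrap") 5 else 10
  matches <- stage("match",
                   match_features(features, db, ppm_tol = ppm_tol,
                                  adduct = cfg$adduct))
  out$matches <- emit("matches", matches)

  retained <- stage("blank_filter", blank_filter(features, cfg$blank_ratio))
  matches <- dplyr::filter(matches, .data$feature_id %in% retained)

  fp <- stage("ksw", build_fingerprints(
    features, matches,
    panel = db_solvents(db),
    volume_correction = cfg$volume_correction
  ))
  out$fingerprints <- emit("fingerprints", fp)

  imputed <- stage("impute", impute_fingerprints(
    fp, db, n_iter = cfg$imputation$n_iter, seed = cfg$imputation$seed
  ))
  out$imputed <- emit("fingerprints_imputed", imputed)

  complete_ids <- imputed |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::filter(!anyNA(.data$value)) |>
    dplyr::ungroup()
  std <- stage("standardize", standardize_fingerprints(complete_ids))
  out$standardized <- emit("fingerprints_std", std)

  theo <- db |>
    dplyr::select("compound_id", dplyr::starts_with("logK_")) |>
    tidyr::pivot_longer(dplyr::starts_with("logK_"), names_to = "solvent",
                        values_to = "value",
                        names_prefix = "logK_") |>
    dplyr::mutate(imputed = FALSE, standardized = FALSE)
  theo_std <- standardize_fingerprints(
    dplyr::semi_join(theo, std, by = "compound_id")
  )
  comparisons <- stage("compare", compare_fingerprints(std, theo_std))
  out$comparisons <- emit("comparisons", comparisons)

  isomers <- if (!is.null(cfg$paths$isomers)) {
    stage("priors", read_isomers(cfg$paths$isomers))
  } else {
    dplyr::select(db, "formula", "data_sources",
                  dplyr::starts_with("frag_"))
  }
  priors <- stage("priors", fragment_priors(isomers))
  out$priors <- emit("priors", priors)

  model_data <- stage("model_data", prepare_model_data(
    std, db, priors = priors, panel = db_solvents(db)
  ))
  if (isTRUE(cfg$model$train)) {
    model <- stage("train", train_fragment_net(
      model_data, epochs = cfg$model$epochs, cv_folds = cfg$model$cv_folds,
      batch_size = cfg$model$batch_size, hidden = cfg$model$hidden,
      n_relu = cfg$model$n_relu, dropout = cfg$model$dropout,
      seed = cfg$model$seed
    ))
    out$model <- model
    save_fragment_net(model, file.path(cfg$paths$out_dir, "model"))
    emit("cv_metrics", tidy(model))
  } else {
    model <- stage("load_model", load_fragment_net(cfg$paths$model_dir))
    out$model <- model
  }

  predictions <- stage("predict", predict_fragments(model, model_data))
  out$predictions <- emit("predictions", predictions)

  truth_cols <- grep("^frag_", names(db), value = TRUE)
  if (length(truth_cols) > 0) {
    evaluation <- stage("evaluate", evaluate_fragments(
      predictions, dplyr::select(db, "compound_id",
                                 dplyr::all_of(truth_cols))
    ))
    out$evaluation <- emit("evaluation", evaluation)
  }

  provenance <- list(
    package = "partprint",
    version = as.character(utils::packageVersion("partprint")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg,
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(provenance,
                       file.path(cfg$paths$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}

validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$paths)) stop("config needs a 'paths' block")
  defaults <- list(
    platform = "qtof", adduct = "[M+H]+", blank_ratio = 1.3,
    volume_correction = TRUE,
    imputation = list(n_iter = 100, seed = 1),
    model = list(train = TRUE, epochs = 200, cv_folds = 5, batch_size = 32,
                 hidden = 500, n_relu = 10, dropout = 0.2, seed = 1)
  )
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$platform %in% c("qtof", "orbitrap")) {
    stop("platform must be 'qtof' or 'orbitrap'")
  }
  for (p in c("features", "manifest", "reference_db")) {
    if (is.null(cfg$paths[[p]])) stop("config paths block lacks '", p, "'")
    if (!file.exists(cfg$paths[[p]])) {
      stop("configured ", p, " file does not exist: ", cfg$paths[[p]])
    }
  }
  if (!isTRUE(cfg$model$train) && is.null(cfg$paths$model_dir)) {
    stop("model.train is false but no paths.model_dir is configured")
  }
  if (is.null(cfg$paths$out_dir)) stop("config paths block lacks 'out_dir'")
  cfg
}

#' Write a simulated panel to disk
#'
#' Emits the rendered feature table, manifest, reference database and
#' ground-truth tables of a [simulate_panel()] result in the same CSV
#' dialects the readers consume, so a simulated study can be run through
#' [run_pipeline()] like a real one.
#'
#' @param panel A `sim_panel`.
#' @param dir Output directory.
#'
#' @return Invisibly, a named list of the files written.
#' @export
write_sim_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sim_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    features = file.path(dir, "features.csv"),
    manifest = file.path(dir, "manifest.csv"),
    reference_db = file.path(dir, "reference_db.csv"),
    isomers = file.path(dir, "isomers.csv"),
    truth_fingerprints = file.path(dir, "truth_fingerprints.csv"),
    truth_rrf = file.path(dir, "truth_rrf.csv")
  )
  write_feature_table(panel$features, paths$features, paths$manifest)
  write_reference_db(panel$reference_db, paths$reference_db)
  readr::write_csv(panel$isomers, paths$isomers, progress = FALSE)
  readr::write_csv(panel$fingerprints, paths$truth_fingerprints,
                   progress = FALSE)
  readr::write_csv(panel$rrf, paths$truth_rrf, progress = FALSE)
  invisible(paths)
}
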