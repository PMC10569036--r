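#' Read an aligned feature table with its sample manifest
#'
#' Reads an MS-DIAL-style alignment export (one row per feature, one column
#' per sample) together with a sample-role manifest, validates the two
#' against each other, and returns a tidy long table with one row per
#' (feature, sample) measurement.
#'
#' The feature CSV/TSV must contain columns `feature_id`, `mz`, `rt`, plus
#' one numeric column per sample. The manifest must contain `sample_id`,
#' `role` (one of `partition`, `water_control`, `blank`), `solvent`,
#' `replicate`, `injection`, and may carry `v_w`/`v_s` (mL) phase volumes.
#' Feature-table columns not named in the manifest (beyond the three fixed
#' ones) are ignored with a warning; manifest samples missing from the table
#' are an error.
#'
#' @param path Path to the feature table (CSV or TSV by extension).
#' @param manifest_path Path to the manifest CSV.
#'
#' @return Long tibble with columns `feature_id`, `mz`, `rt`, `sample_id`,
#'   `area` and the manifest columns.
#' @export
read_feature_table <- function(path, manifest_path) {
  features <- read_delim_auto(path)
  manifest <- read_delim_auto(manifest_path)

  required <- c("feature_id", "mz", "rt")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  req_manifest <- c("sample_id", "role", "solvent", "replicate", "injection")
  missing_m <- setdiff(req_manifest, names(manifest))
  if (length(missing_m) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_m, collapse = ", "))
  }
  bad_roles <- setdiff(unique(manifest$role),
                       c("partition", "water_control", "blank"))
  if (length(bad_roles) > 0) {
    stop("unknown sample role(s) in manifest: ",
         paste(bad_roles, collapse = ", "))
  }

  sample_cols <- setdiff(names(features), required)
  not_in_table <- setdiff(manifest$sample_id, sample_cols)
  if (length(not_in_table) > 0) {
    stop("manifest sample(s) absent from feature table: ",
         paste(not_in_table, collapse = ", "))
  }
  extra <- setdiff(sample_cols, manifest$sample_id)
  if (length(extra) > 0) {
    warning("ignoring feature-table column(s) not in manifest: ",
            paste(extra, collapse = ", "))
    features <- features[c(required, manifest$sample_id)]
  }

  dup <- manifest |>
    dplyr::filter(.data$role %in% c("partition", "water_control")) |>
    dplyr::count(.data$role, .data$solvent, .data$replicate, .data$injection) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("manifest assigns more than one sample to the same ",
         "(role, solvent, replicate, injection) slot")
  }

  long <- features |>
    tidyr::pivot_longer(-dplyr::all_of(required),
                        names_to = "sample_id", values_to = "area") |>
    dplyr::left_join(manifest, by = "sample_id")
  if (any(is.na(long$area)) || any(long$area < 0)) {
    stop("feature table contains missing or negative areas")
  }
  long
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a feature table and manifest
#'
#' Inverse of [read_feature_table()]: pivots a long measurement table back
#' into the wide one-column-per-sample layout and writes the manifest beside
#' it.
#'
#' @param features Long tibble as returned by [read_feature_table()] or
#'   found in a `sim_panel`.
#' @param path Output path for the feature CSV.
#' @param manifest_path Output path for the manifest CSV.
#'
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(features, path, manifest_path) {
  manifest <- features |>
    dplyr::distinct(dplyr::pick(dplyr::any_of(
      c("sample_id", "role", "solvent", "replicate", "injection",
        "v_w", "v_s")
    )))
  wide <- features |>
    dplyr::select("feature_id", "mz", "rt", "sample_id", "area") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "area")
  readr::write_csv(wide, path, progress = FALSE)
  readr::write_csv(manifest, manifest_path, progress = FALSE)
  invisible(c(path, manifest_path))
}

#' Read a compound reference database
#'
#' Reads a curated reference database CSV: compound identifiers, molecular
#' formulas, monoisotopic masses, structure strings, per-solvent theoretical
#' log K_SW values in `logK_<solvent>` columns (missing values allowed) and
#' substructure counts in `frag_<name>` columns.
#'
#' @param path Path to the CSV.
#' @param panel Optional character vector of expected solvent names; solvents
#'   in the file outside this panel are an error.
#'
#' @return Wide tibble, one row per compound.
#' @export
read_reference_db <- function(path, panel = NULL) {
  db <- read_delim_auto(path)
  required <- c("compound_id", "formula", "monoisotopic_mass")
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols) > 0) {
    stop("reference database is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(db$monoisotopic_mass <= 0)) {
    stop("reference database contains non-positive monoisotopic masses")
  }
  solvents <- db_solvents(db)
  if (!is.null(panel)) {
    extra <- setdiff(solvents, panel)
    if (length(extra) > 0) {
      stop("reference database has solvents outside the declared panel: ",
           paste(extra, collapse = ", "))
    }
  }
  frag_cols <- grep("^frag_", names(db), value = TRUE)
  if (length(frag_cols) > 0) {
    fr <- as.matrix(db[frag_cols])
    if (any(fr < 0, na.rm = TRUE) || any(fr != round(fr), na.rm = TRUE)) {
      stop("fragment counts in the reference database must be ",
           "non-negative integers")
    }
  }
  db
}

#' Write a compound reference database
#'
#' @param db Wide reference-database tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_reference_db <- function(db, path) {
  readr::write_csv(db, path, progress = FALSE)
  invisible(path)
}

# Solvent names covered by a wide reference db (logK_ columns).
db_solvents <- function(db) {
  sub("^logK_", "", grep("^logK_", names(db), value = TRUE))
}

#' Match features to reference compounds by monoisotopic mass
#'
#' Compares adduct-corrected feature m/z values against the theoretical
#' monoisotopic masses of reference compounds within a relative (ppm) mass
#' tolerance. All qualifying (feature, compound) pairs are returned; no
#' winner is picked when several candidates fall inside the window.
#'
#' The ppm error uses the theoretical monoisotopic mass as denominator
#' (matching is against known candidates), i.e.
#' `1e6 * |mz_neutral - mass| / mass`, where `mz_neutral` removes the
#' configured adduct: `[M+H]+` subtracts and `[M-H]-` adds one proton mass.
#'
#' @param features Tibble with at least `feature_id` and `mz` (long or wide;
#'   duplicate feature rows are collapsed).
#' @param db Reference database tibble (`compound_id`, `monoisotopic_mass`).
#' @param ppm_tol Mass tolerance in ppm; 10 suits a QTOF, 5 an Orbitrap.
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"none"` (`mz` already
#'   neutral).
#'
#' @return Tibble with columns `feature_id`, `compound_id`, `ppm_error`.
#' @export
#'
#' @examples
#' feats <- tibble::tibble(feature_id = "F1", mz = 300.003)
#' db <- tibble::tibble(compound_id = "A", monoisotopic_mass = 300)
#' match_features(feats, db, ppm_tol = 10, adduct = "none")
match_features <- function(features, db, ppm_tol = 10,
                           adduct = c("[M+H]+", "[M-H]-", "none")) {
  adduct <- match.arg(adduct)
  stopifnot(ppm_tol > 0)
  if (nrow(db) == 0) {
    warning("empty reference database; no matches possible")
    return(tibble::tibble(feature_id = character(),
                          compound_id = character(),
                          ppm_error = numeric()))
  }
  shift <- switch(adduct, "[M+H]+" = -PROTON_MASS, "[M-H]-" = PROTON_MASS,
                  none = 0)
  feats <- dplyr::distinct(features, .data$feature_id, .data$mz) |>
    dplyr::mutate(mz_neutral = .data$mz + shift)
  tidyr::expand_grid(
    feats,
    dplyr::select(db, "compound_id", "monoisotopic_mass")
  ) |>
    dplyr::mutate(ppm_error = 1e6 * (.data$mz_neutral - .data$monoisotopic_mass) /
                    .data$monoisotopic_mass) |>
    # tiny relative slack keeps the inclusive boundary robust to the
    # floating-point rounding of the ppm-error quotient itself
    dplyr::filter(abs(.data$ppm_error) <= ppm_tol * (1 + 1e-9)) |>
    dplyr::select("feature_id", "compound_id", "ppm_error")
}

#' Blank-filter features
#'
#' Retains a feature when its reference signal is at least `ratio` times the
#' mean blank area. The reference signal is the largest water-control area
#' observed for the feature (water controls carry the full spiked amount and
#' are the natural true-positive reference); the comparison is inclusive, and
#' a zero mean blank area always retains the feature.
#'
#' @param features Long feature tibble (from [read_feature_table()] or a
#'   `sim_panel`) with `role` and `area` columns.
#' @param ratio Retention threshold; the conventional value is 1.3.
#'
#' @return Character vector of retained `feature_id`s.
#' @export
blank_filter <- function(features, ratio = 1.3) {
  stopifnot(ratio >= 1)
  if (!any(features$role == "blank")) {
    stop("no blank samples present; blank filtering needs at least one")
  }
  stats_tbl <- features |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      ref = max(.data$area[.data$role == "water_control"], 0),
      blank = mean(.data$area[.data$role == "blank"]),
      .groups = "drop"
    )
  stats_tbl |>
    dplyr::filter(.data$blank == 0 | .data$ref >= ratio * .data$blank) |>
    dplyr::pull("feature_id")
}
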