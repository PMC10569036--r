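#' Solvent-phase peak area by difference
#'
#' The solvent-phase area of an analyte is inferred from aqueous-phase
#' measurements only: the water-control area (total spiked analyte, `a_t`)
#' minus the post-equilibration aqueous area (`a_w`). Non-positive
#' differences mean the analyte did not measurably partition (or the areas
#' are dominated by noise) and are returned as `NA`, which routes the entry
#' to the imputation path downstream; missingness is a value here, not an
#' error.
#'
#' @param a_t Water-control (total) peak area, >= 0.
#' @param a_w Aqueous-phase peak area after equilibration, >= 0.
#'
#' @return `a_t - a_w`, or `NA` where the difference is <= 0. Vectorized.
#' @export
#'
#' @examples
#' solvent_area(200, 100) # 100
#' solvent_area(100, 100) # NA: nothing measurably partitioned
solvent_area <- function(a_t, a_w) {
  stopifnot(all(a_t >= 0, na.rm = TRUE), all(a_w >= 0, na.rm = TRUE))
  a_s <- a_t - a_w
  a_s[is.na(a_s) | a_s <= 0] <- NA_real_
  a_s
}

#' log10 solvent-water partition ratio from peak areas
#'
#' Computes `log10(((a_t - a_w) / a_w) * (v_w / v_s))`: the area ratio
#' estimates the amount ratio between the phases, and the volume ratio
#' converts amounts to concentrations so that replicates run at different
#' solvent:water ratios are comparable. Both areas are measured in the
#' aqueous matrix, so the analyte's response factor cancels. For ionizable
#' compounds the result is operationally a log distribution ratio (log D_SW)
#' at the working pH.
#'
#' Set `volume_correction = FALSE` to drop the `v_w / v_s` factor and use the
#' bare area ratio.
#'
#' @param a_t Water-control (total) peak area.
#' @param a_w Aqueous-phase peak area after equilibration.
#' @param v_w Water volume (mL), > 0.
#' @param v_s Solvent volume (mL), > 0.
#' @param volume_correction Apply the phase-volume ratio (default `TRUE`).
#'
#' @return log10 partition ratio, or `NA` when `a_t - a_w <= 0` or
#'   `a_w <= 0`. Vectorized.
#' @export
#'
#' @examples
#' log_ksw(200, 100)                 # 0: equal amounts in both phases
#' log_ksw(1100, 100)                # 1
#' log_ksw(150, 100, v_w = 1, v_s = 2) # log10(0.25)
log_ksw <- function(a_t, a_w, v_w = 1, v_s = 1, volume_correction = TRUE) {
  stopifnot(all(v_w > 0, na.rm = TRUE), all(v_s > 0, na.rm = TRUE))
  a_s <- solvent_area(a_t, a_w)
  ratio <- a_s / a_w
  ratio[!is.na(a_w) & a_w <= 0] <- NA_real_
  if (volume_correction) ratio <- ratio * (v_w / v_s)
  log10(ratio)
}

#' Aggregate per-replicate log partition ratios
#'
#' Replicates are averaged in log space (each replicate's log K_SW is an
#' independent estimate of the same log-scale quantity); missing replicates
#' are dropped, and the result is missing only when every replicate is.
#'
#' @param x Numeric vector of per-replicate log10 partition ratios (may
#'   contain `NA`).
#'
#' @return Tibble with columns `value` (mean of non-missing logs), `n_used`,
#'   and `sd` (`NA` when fewer than 2 replicates contribute).
#' @export
#'
#' @examples
#' aggregate_replicates(c(0.9, NA, 1.1))
aggregate_replicates <- function(x) {
  ok <- !is.na(x)
  tibble::tibble(
    value = if (any(ok)) mean(x[ok]) else NA_real_,
    n_used = sum(ok),
    sd = if (sum(ok) >= 2) sd(x[ok]) else NA_real_
  )
}

#' Build partition fingerprints from a matched feature table
#'
#' Assembles one solvent-panel fingerprint per matched compound: injection
#' duplicates are averaged in area space, the per-replicate log K_SW is
#' computed from the water-control and partition areas (with the replicate's
#' phase volumes), and replicates are averaged in log space. The output is
#' panel-complete: every (compound, solvent) pair appears, with `NA` marking
#' missing entries.
#'
#' An aqueous-phase or water-control area at or below the feature's mean
#' blank area is treated as undetected (the entry becomes missing rather
#' than a noise-driven value); disable with `blank_guard = FALSE`.
#'
#' A compound matched to more than one feature triggers a warning; the
#' feature with the smallest absolute ppm error is used, with the highest
#' total water-control area breaking ties.
#'
#' @param features Long feature tibble (see [read_feature_table()]).
#' @param matches Match tibble from [match_features()].
#' @param panel Character vector of panel solvents; defaults to those present
#'   in `features`.
#' @param volume_correction Apply phase-volume correction (see [log_ksw()]).
#' @param blank_guard Treat areas at or below the blank level as undetected.
#'
#' @return Fingerprint tibble: `compound_id`, `solvent`, `value`, `n_used`,
#'   `sd`, `imputed` (all `FALSE` here), `standardized` (all `FALSE`).
#' @export
build_fingerprints <- function(features, matches,
                               panel = NULL,
                               volume_correction = TRUE,
                               blank_guard = TRUE) {
  if (is.null(panel)) {
    panel <- sort(unique(stats::na.omit(features$solvent)))
  }
  if (nrow(matches) == 0) {
    return(empty_fingerprint_tbl())
  }

  # Resolve compound -> single feature: closest accurate mass first, then
  # the strongest water-control signal as a tie-breaker.
  strength <- features |>
    dplyr::filter(.data$role == "water_control") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(total_area = sum(.data$area), .groups = "drop")
  if (!"ppm_error" %in% names(matches)) matches$ppm_error <- 0
  resolved <- matches |>
    dplyr::left_join(strength, by = "feature_id") |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::arrange(abs(.data$ppm_error), dplyr::desc(.data$total_area),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  n_ambig <- sum(table(matches$compound_id) > 1)
  if (n_ambig > 0) {
    warning(n_ambig, " compound(s) matched several features; ",
            "using the closest-mass feature for each")
  }

  blank_mean <- features |>
    dplyr::filter(.data$role == "blank") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(blank = mean(.data$area), .groups = "drop")

  has_vol <- all(c("v_w", "v_s") %in% names(features))
  meas <- features |>
    dplyr::filter(.data$role %in% c("partition", "water_control"),
                  !is.na(.data$solvent)) |>
    dplyr::semi_join(resolved, by = "feature_id") |>
    dplyr::left_join(dplyr::select(resolved, "feature_id", "compound_id"),
                     by = "feature_id",
                     relationship = "many-to-many") |>
    dplyr::left_join(blank_mean, by = "feature_id") |>
    dplyr::mutate(blank = dplyr::coalesce(.data$blank, 0)) |>
    dplyr::group_by(.data$compound_id, .data$feature_id, .data$solvent,
                    .data$replicate, .data$role) |>
    dplyr::summarise(
      area = mean(.data$area),
      v_w = if (has_vol) .data$v_w[1] else 1,
      v_s = if (has_vol) .data$v_s[1] else 1,
      blank = .data$blank[1],
      .groups = "drop"
    )

  per_rep <- meas |>
    tidyr::pivot_wider(names_from = "role", values_from = "area") |>
    dplyr::mutate(
      partition = if (blank_guard) {
        ifelse(.data$partition <= .data$blank, NA_real_, .data$partition)
      } else .data$partition,
      water_control = if (blank_guard) {
        ifelse(.data$water_control <= .data$blank, NA_real_,
               .data$water_control)
      } else .data$water_control,
      log_k = log_ksw(.data$water_control, .data$partition,
                      v_w = dplyr::coalesce(.data$v_w, 1),
                      v_s = dplyr::coalesce(.data$v_s, 1),
                      volume_correction = volume_correction)
    )

  agg <- per_rep |>
    dplyr::group_by(.data$compound_id, .data$solvent) |>
    dplyr::summarise(aggregate_replicates(.data$log_k), .groups = "drop")

  tidyr::expand_grid(
    compound_id = unique(resolved$compound_id),
    solvent = panel
  ) |>
    dplyr::left_join(agg, by = c("compound_id", "solvent")) |>
    dplyr::mutate(
      n_used = dplyr::coalesce(.data$n_used, 0L),
      imputed = FALSE,
      standardized = FALSE
    ) |>
    dplyr::arrange(.data$compound_id,
                   match(.data$solvent, panel))
}

empty_fingerprint_tbl <- function() {
  tibble::tibble(compound_id = character(), solvent = character(),
                 value = numeric(), n_used = integer(), sd = numeric(),
                 imputed = logical(), standardized = logical())
}

#' Write / read fingerprint tables
#'
#' Fingerprints travel as long-format CSV: one row per (compound, solvent)
#' with `value`, `n_used`, `sd`, `imputed` and `standardized` columns.
#'
#' @param fp Fingerprint tibble.
#' @param path CSV path.
#' @return `write_fingerprints()` invisibly returns `path`;
#'   `read_fingerprints()` returns the tibble.
#' @export
write_fingerprints <- function(fp, path) {
  readr::write_csv(fp, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  fp <- read_delim_auto(path)
  req <- c("compound_id", "solvent", "value")
  missing_cols <- setdiff(req, names(fp))
  if (length(missing_cols) > 0) {
    stop("fingerprint table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"imputed" %in% names(fp)) fp$imputed <- FALSE
  if (!"standardized" %in% names(fp)) fp$standardized <- FALSE
  fp
}
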