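#' Standardize fingerprints across the solvent axis
#'
#' Z-scores each compound's fingerprint across its non-missing solvents
#' (removing the mean, scaling to unit variance; population variance). For
#' an ionizable compound, the measured log D_SW differs from the neutral
#' log K_SW by the same additive offset `log10(f_u)` in every solvent, so
#' per-compound standardization makes the two identical: post-standardization
#' D and K values are interchangeable, which is what lets distribution-ratio
#' measurements feed a model trained on partition ratios.
#'
#' @param fp Fingerprint tibble (long format; `NA` marks missing entries).
#'
#' @return The same tibble with `value` z-scored per compound and
#'   `standardized = TRUE`. The missing mask is preserved. Standardizing an
#'   already standardized fingerprint is the identity (within rounding).
#' @export
#'
#' @examples
#' fp <- tibble::tibble(compound_id = "A", solvent = c("s1", "s2", "s3"),
#'                      value = c(1, 2, 3), imputed = FALSE,
#'                      standardized = FALSE)
#' standardize_fingerprints(fp)$value # -1.2247, 0, 1.2247
standardize_fingerprints <- function(fp) {
  stopifnot(all(c("compound_id", "solvent", "value") %in% names(fp)))
  if (!"standardized" %in% names(fp)) fp$standardized <- FALSE
  fp |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::group_modify(function(d, key) {
      x <- d$value
      ok <- !is.na(x)
      if (sum(ok) < 2) {
        stop("compound '", key$compound_id[1],
             "' has fewer than 2 observed solvents; cannot standardize")
      }
      mu <- mean(x[ok])
      sigma <- sqrt(mean((x[ok] - mu)^2)) # population SD
      if (sigma == 0) {
        stop("compound '", key$compound_id[1],
             "' has zero variance across solvents; cannot standardize")
      }
      d$value <- (x - mu) / sigma
      d$standardized <- TRUE
      d
    }) |>
    dplyr::ungroup()
}

#' Compare observed and theoretical fingerprints
#'
#' For each compound present in both inputs, regresses the theoretical
#' fingerprint on the observed one (ordinary least squares over the common
#' non-missing solvents) and reports the squared Pearson correlation, the
#' mean absolute difference, and the regression slope and intercept. When
#' both inputs are standardized, the intercept is 0 and the slope equals the
#' Pearson correlation by construction.
#'
#' Compounds with fewer than `min_n` common solvents are dropped (the
#' comparison is undefined for them); a message reports how many.
#'
#' @param obs Observed fingerprint tibble (x variable).
#' @param theo Theoretical fingerprint tibble (y variable).
#' @param min_n Minimum number of common non-missing solvents (default 3).
#'
#' @return Tibble with columns `compound_id`, `r2`, `mae`, `slope`,
#'   `intercept`, `n`, `standardized` (TRUE when both inputs were).
#' @export
compare_fingerprints <- function(obs, theo, min_n = 3) {
  stopifnot(min_n >= 3)
  both_std <- all(obs$standardized) && all(theo$standardized)
  paired <- dplyr::inner_join(
    dplyr::select(obs, "compound_id", "solvent", obs_value = "value"),
    dplyr::select(theo, "compound_id", "solvent", theo_value = "value"),
    by = c("compound_id", "solvent")
  ) |>
    dplyr::filter(!is.na(.data$obs_value), !is.na(.data$theo_value))

  counts <- dplyr::count(paired, .data$compound_id)
  dropped <- counts$compound_id[counts$n < min_n]
  if (length(dropped) > 0) {
    message(length(dropped), " compound(s) dropped from comparison ",
            "(fewer than ", min_n, " common solvents)")
  }

  paired |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::filter(dplyr::n() >= min_n) |>
    dplyr::summarise(
      r2 = cor(.data$obs_value, .data$theo_value)^2,
      mae = mean(abs(.data$obs_value - .data$theo_value)),
      slope = cov(.data$obs_value, .data$theo_value) /
        var(.data$obs_value),
      intercept = mean(.data$theo_value) -
        cov(.data$obs_value, .data$theo_value) / var(.data$obs_value) *
          mean(.data$obs_value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(standardized = both_std)
}

#' Select compounds reproducible across platforms
#'
#' Filters a fingerprint comparison table (e.g. QTOF vs Orbitrap
#' fingerprints of the same compounds) to the compounds whose agreement
#' reaches the threshold. The boundary is inclusive.
#'
#' @param comparisons Output of [compare_fingerprints()].
#' @param threshold Minimum Pearson R-squared (default 0.8).
#'
#' @return Character vector of retained compound ids.
#' @export
cross_platform_select <- function(comparisons, threshold = 0.8) {
  comparisons |>
    dplyr::filter(.data$r2 >= threshold) |>
    dplyr::pull("compound_id")
}

#' Infer a distribution ratio from an anchor pair
#'
#' Because the ionized fraction of a compound lives in the aqueous phase
#' only, the difference between two solvent systems' log distribution ratios
#' is pH-independent and equals the difference of the neutral log partition
#' ratios. Knowing one system's distribution ratio at a pH therefore fixes
#' the other's:
#' `log D_target(pH) = log K_target + (log D_anchor(pH) - log K_anchor)`.
#'
#' @param logk_target log K of the target solvent system.
#' @param logk_anchor log K of the anchor solvent system.
#' @param logd_anchor log D of the anchor system at the pH of interest.
#'
#' @return log D of the target system at that pH. Vectorized.
#' @export
#'
#' @examples
#' infer_distribution_ratio(3, 2, 1.5) # 2.5
infer_distribution_ratio <- function(logk_target, logk_anchor, logd_anchor) {
  stopifnot(all(is.finite(logk_target)), all(is.finite(logk_anchor)),
            all(is.finite(logd_anchor)))
  logk_target + (logd_anchor - logk_anchor)
}
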