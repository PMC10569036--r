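#' Normalize literature-popularity scores within a formula
#'
#' Each isomer of a molecular formula carries a non-negative
#' `data_sources` count (how many independent sources report the
#' structure). Within a formula the counts are scaled to `[0, 1]` by
#' dividing by the maximum, so the best-documented isomer gets weight 1 and
#' every isomer keeps a positive weight. When all counts are zero the
#' isomers are weighted uniformly at 1.
#'
#' @param isomers Tibble with columns `formula`, `smiles` (or any structure
#'   id) and `data_sources`.
#'
#' @return The input with an added `weight` column in `[0, 1]`.
#' @export
#'
#' @examples
#' iso <- tibble::tibble(formula = "C6H6O", smiles = c("a", "b"),
#'                       data_sources = c(40, 10))
#' normalize_sources(iso)$weight # 1.0, 0.25
normalize_sources <- function(isomers) {
  stopifnot(all(c("formula", "data_sources") %in% names(isomers)),
            all(isomers$data_sources >= 0))
  isomers |>
    dplyr::group_by(.data$formula) |>
    dplyr::mutate(
      weight = if (max(.data$data_sources) == 0) 1
               else .data$data_sources / max(.data$data_sources)
    ) |>
    dplyr::ungroup()
}

#' Fragment likelihood priors per molecular formula
#'
#' Converts isomer metadata into per-formula substructure priors: each
#' isomer's integer fragment counts are weighted by its normalized
#' `data_sources` score and summed over the formula's isomers. The result
#' scores how likely each fragment is to occur in a structure with that
#' formula, weighted toward well-documented structures; it feeds the
#' prediction model as an additional input block.
#'
#' @param isomers Tibble with `formula`, `data_sources` and `frag_<name>`
#'   count columns (non-negative integers).
#' @param normalization `"max"` (default; divide by the formula's maximum
#'   count, keeping all isomers at positive weight) or `"minmax"`
#'   (min-max scaling, which zeroes out the least-documented isomer).
#'
#' @return Tibble with one row per formula: `formula`, `n_isomers`, and the
#'   weighted-sum `frag_<name>` columns (non-negative reals).
#' @export
#'
#' @examples
#' iso <- tibble::tibble(
#'   formula = "C6H6O", data_sources = c(40, 10),
#'   frag_ring = c(1, 2), frag_oh = c(2, 0)
#' )
#' fragment_priors(iso) # ring: 1*1 + 2*0.25 = 1.5; oh: 2
fragment_priors <- function(isomers, normalization = c("max", "minmax")) {
  normalization <- match.arg(normalization)
  frag_cols <- grep("^frag_", names(isomers), value = TRUE)
  if (length(frag_cols) == 0) {
    stop("isomer table has no frag_* columns")
  }
  fr <- as.matrix(isomers[frag_cols])
  if (any(fr < 0) || any(fr != round(fr))) {
    stop("isomer fragment counts must be non-negative integers")
  }

  weighted <- if (normalization == "max") {
    normalize_sources(isomers)
  } else {
    isomers |>
      dplyr::group_by(.data$formula) |>
      dplyr::mutate(
        weight = {
          rng <- range(.data$data_sources)
          if (rng[1] == rng[2]) rep(1, dplyr::n())
          else (.data$data_sources - rng[1]) / (rng[2] - rng[1])
        }
      ) |>
      dplyr::ungroup()
  }

  weighted |>
    dplyr::group_by(.data$formula) |>
    dplyr::summarise(
      n_isomers = dplyr::n(),
      dplyr::across(dplyr::all_of(frag_cols), ~ sum(.x * weight)),
      .groups = "drop"
    )
}

#' Read / write isomer metadata and fragment priors
#'
#' Isomer CSVs carry `formula`, `smiles`, `data_sources` and `frag_<name>`
#' columns; prior CSVs carry `formula` plus `frag_<name>` columns.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_isomers <- function(path) {
  iso <- read_delim_auto(path)
  req <- c("formula", "data_sources")
  missing_cols <- setdiff(req, names(iso))
  if (length(missing_cols) > 0) {
    stop("isomer table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  iso
}

#' @rdname read_isomers
#' @param priors Prior tibble from [fragment_priors()].
#' @export
write_priors <- function(priors, path) {
  readr::write_csv(priors, path, progress = FALSE)
  invisible(path)
}
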