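#' Plot partition fingerprints
#'
#' Draws each compound's fingerprint as a line over the solvent panel;
#' imputed entries are marked with open symbols.
#'
#' @param fp Fingerprint tibble (long format).
#' @param compounds Optional character vector restricting the plot.
#'
#' @return A ggplot object.
#' @export
plot_fingerprints <- function(fp, compounds = NULL) {
  if (!is.null(compounds)) {
    fp <- dplyr::filter(fp, .data$compound_id %in% compounds)
  }
  ylab <- if (all(fp$standardized)) "standardized log K" else
    expression(log[10] ~ K[SW])
  ggplot2::ggplot(
    dplyr::filter(fp, !is.na(.data$value)),
    ggplot2::aes(x = .data$solvent, y = .data$value,
                 group = .data$compound_id, colour = .data$compound_id)
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$imputed), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = NULL, y = ylab, shape = "imputed",
                  colour = "compound") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot fingerprint-comparison distributions
#'
#' Histograms of the per-compound agreement metrics between observed and
#' theoretical fingerprints, with the cross-platform selection threshold
#' marked on the R-squared panel.
#'
#' @param comparisons Output of [compare_fingerprints()].
#' @param threshold Selection threshold drawn as a reference line.
#'
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparisons, threshold = 0.8) {
  long <- comparisons |>
    dplyr::select("compound_id", "r2", "mae") |>
    tidyr::pivot_longer(c("r2", "mae"), names_to = "metric")
  ref <- tibble::tibble(metric = "r2", x = threshold)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(data = ref,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "compounds") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs true fragment counts for selected compounds
#'
#' Side-by-side bars of the decimal predictions and the integer truth, one
#' facet per compound.
#'
#' @param pred Prediction tibble from [predict_fragments()].
#' @param truth Tibble with `compound_id` and true `frag_<name>` counts.
#' @param compounds Character vector of compounds to show.
#'
#' @return A ggplot object.
#' @export
plot_fragment_prediction <- function(pred, truth, compounds) {
  frag_cols <- grep("^frag_", names(pred), value = TRUE)
  stack <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(pred, "compound_id",
                                dplyr::all_of(frag_cols)),
                  kind = "predicted"),
    dplyr::mutate(dplyr::select(truth, "compound_id",
                                dplyr::all_of(frag_cols)),
                  kind = "true")
  ) |>
    dplyr::filter(.data$compound_id %in% compounds) |>
    tidyr::pivot_longer(dplyr::all_of(frag_cols), names_to = "fragment") |>
    dplyr::mutate(fragment = sub("^frag_", "", .data$fragment))
  ggplot2::ggplot(stack, ggplot2::aes(x = .data$fragment, y = .data$value,
                                      fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(predicted = "grey55",
                                          true = "firebrick")) +
    ggplot2::facet_wrap(~compound_id) +
    ggplot2::labs(x = NULL, y = "fragment count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Autoplot method for trained fragment models
#'
#' Boxplots of the per-fragment test metrics across the shuffle-split
#' folds.
#'
#' @param object A trained `fragment_net`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot fragment_net
#' @export
autoplot.fragment_net <- function(object, ...) {
  m <- tidy(object) |>
    tidyr::pivot_longer(c("r2", "mae"), names_to = "metric")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$fragment, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Held-out fragment prediction metrics by fold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
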