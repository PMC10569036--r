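#' Assemble model inputs and targets for the fragment-count network
#'
#' Joins standardized fingerprints, compound metadata and per-formula
#' fragment priors into one wide modelling table: one row per compound with
#' input blocks `fp_<solvent>` (the standardized fingerprint),
#' `mass` (monoisotopic mass), `el_<element>` (the molecular-formula
#' encoding over the fixed element alphabet) and `prior_<fragment>` (the
#' formula's fragment-likelihood prior), plus target columns `frag_<name>`
#' when `compounds` carries true fragment counts.
#'
#' The fingerprint must be complete: a missing solvent value would propagate
#' `NaN` through the network, so incomplete compounds are an error directing
#' to [impute_fingerprints()].
#'
#' @param fp Standardized fingerprint tibble (long format, panel-complete).
#' @param compounds Tibble with `compound_id`, `formula`,
#'   `monoisotopic_mass` and optionally `frag_<name>` target columns.
#' @param priors Optional per-formula prior tibble from [fragment_priors()];
#'   omitted priors are encoded as zeros.
#' @param panel Solvent panel order for the fingerprint block; defaults to
#'   the solvents present in `fp`.
#'
#' @return Wide tibble, one row per compound.
#' @export
prepare_model_data <- function(fp, compounds, priors = NULL, panel = NULL) {
  if (!all(fp$standardized)) {
    stop("fingerprints must be standardized before modelling; ",
         "see standardize_fingerprints()")
  }
  if (is.null(panel)) panel <- unique(fp$solvent)
  wide_fp <- fp |>
    dplyr::select("compound_id", "solvent", "value") |>
    dplyr::filter(.data$solvent %in% panel) |>
    tidyr::pivot_wider(names_from = "solvent", values_from = "value",
                       names_prefix = "fp_")
  if (anyNA(wide_fp)) {
    bad <- wide_fp$compound_id[!complete.cases(wide_fp)]
    stop("incomplete fingerprints for ", length(bad), " compound(s) (e.g. ",
         paste(head(bad, 3), collapse = ", "),
         "); impute missing solvents first with impute_fingerprints()")
  }

  el <- parse_formula(compounds$formula)
  colnames(el) <- paste0("el_", colnames(el))
  meta <- compounds |>
    dplyr::select("compound_id", "formula", mass = "monoisotopic_mass") |>
    dplyr::bind_cols(tibble::as_tibble(el))

  out <- dplyr::inner_join(wide_fp, meta, by = "compound_id")

  frag_cols <- grep("^frag_", names(compounds), value = TRUE)
  if (!is.null(priors)) {
    p <- priors |>
      dplyr::select("formula", dplyr::starts_with("frag_")) |>
      dplyr::rename_with(~ sub("^frag_", "prior_", .x),
                         dplyr::starts_with("frag_"))
    out <- dplyr::left_join(out, p, by = "formula")
    prior_cols <- grep("^prior_", names(out), value = TRUE)
    out <- out |>
      dplyr::mutate(dplyr::across(dplyr::all_of(prior_cols),
                                  ~ dplyr::coalesce(.x, 0)))
  } else if (length(frag_cols) > 0) {
    for (fc in frag_cols) out[[sub("^frag_", "prior_", fc)]] <- 0
  }

  if (length(frag_cols) > 0) {
    out <- dplyr::left_join(
      out,
      dplyr::select(compounds, "compound_id", dplyr::all_of(frag_cols)),
      by = "compound_id"
    )
  }
  dplyr::select(out, -"formula")
}

#' Build the fragment-count network
#'
#' Constructs the untrained network: 1 input layer, 10 hidden layers of 500
#' ReLU units, 1 dropout layer, 1 further hidden layer of 500 units with an
#' exponential activation (biasing activations positive, as counts are), and
#' 1 linear output layer whose predictions are clamped at zero at inference.
#' Training uses the Adamax optimizer with step 0.001 and a mean absolute
#' error loss.
#'
#' @param input_size Number of input columns.
#' @param catalog Character vector of output fragment names.
#' @param hidden Width of the hidden layers.
#' @param n_relu Number of ReLU hidden layers.
#' @param dropout Dropout rate applied after the last ReLU layer.
#' @param seed Seed for weight initialization (same seed, same weights).
#'
#' @return Object of class `fragment_net` (untrained).
#' @export
build_fragment_net <- function(input_size, catalog, hidden = 500,
                               n_relu = 10, dropout = 0.2, seed = NULL) {
  stopifnot(input_size > 0, length(catalog) > 0)
  net <- mlp_init(input_size, length(catalog), hidden = hidden,
                  n_relu = n_relu, dropout = dropout, seed = seed)
  structure(
    list(
      net = net, catalog = catalog, input_cols = NULL, scaling = NULL,
      trained = FALSE, report = NULL,
      config = list(hidden = hidden, n_relu = n_relu, dropout = dropout,
                    lr = 0.001, optimizer = "adamax", loss = "mae",
                    seed = seed)
    ),
    class = "fragment_net"
  )
}

#' Layer audit of a fragment network
#'
#' @param model A `fragment_net`.
#' @return Tibble with one row per layer: `layer`, `type`, `units`,
#'   `activation`.
#' @export
net_layers <- function(model) {
  stopifnot(inherits(model, "fragment_net"))
  cfg <- model$config
  dims <- model$net$dims
  tibble::tibble(
    layer = seq_len(cfg$n_relu + 4L),
    type = c("input", rep("dense", cfg$n_relu), "dropout", "dense", "dense"),
    units = c(dims[1], rep(cfg$hidden, cfg$n_relu), cfg$hidden, cfg$hidden,
              dims[length(dims)]),
    activation = c("-", rep("relu", cfg$n_relu), "-", "exponential",
                   "linear")
  )
}

model_input_cols <- function(data) {
  grep("^(fp_|mass$|el_|prior_)", names(data), value = TRUE)
}

scale_inputs <- function(x, scaling) {
  sweep(sweep(x, 2, scaling$mean, "-"), 2, scaling$sd, "/")
}

#' Train the fragment-count network
#'
#' Trains the network of [build_fragment_net()] on a modelling table from
#' [prepare_model_data()] under the standard protocol: an 80/20
#' train/test split repeated as a shuffle-split cross validation
#' (`cv_folds` independent splits), 200 epochs by default, Adamax with step
#' 0.001, MAE loss. Inputs are z-scored column-wise with statistics from
#' each fold's training portion (re-estimated per fold to avoid leakage);
#' the returned model keeps the first fold's network and scaling.
#'
#' @param data Modelling table with input and `frag_<name>` target columns.
#' @param epochs Training epochs per fold.
#' @param cv_folds Number of shuffle-split folds (each an independent 80/20
#'   split).
#' @param train_frac Training fraction of each split.
#' @param batch_size Mini-batch size.
#' @param lr Adamax step size.
#' @param hidden,n_relu,dropout Architecture parameters, see
#'   [build_fragment_net()].
#' @param seed Seed controlling weight init, splits, batch order and
#'   dropout.
#' @param track_loss Record the full-training-set MAE after every epoch.
#'
#' @return A trained `fragment_net`; its `report` element (class
#'   `fragnet_report`) holds per-fold per-fragment test R-squared and MAE,
#'   split sizes, seed, epochs and per-epoch training losses.
#' @export
train_fragment_net <- function(data, epochs = 200, cv_folds = 5,
                               train_frac = 0.8, batch_size = 32,
                               lr = 0.001, hidden = 500, n_relu = 10,
                               dropout = 0.2, seed = 1, track_loss = TRUE) {
  input_cols <- model_input_cols(data)
  target_cols <- grep("^frag_", names(data), value = TRUE)
  if (length(target_cols) == 0) stop("no frag_* target columns in data")
  if (nrow(data) < 50) {
    stop("training needs at least 50 examples; got ", nrow(data))
  }
  x_all <- as.matrix(data[input_cols])
  y_all <- as.matrix(data[target_cols])
  if (anyNA(x_all)) stop("model inputs contain missing values")
  n <- nrow(x_all)
  n_train <- floor(train_frac * n)

  set.seed(seed)
  metrics <- list()
  losses <- list()
  first <- NULL
  for (fold in seq_len(cv_folds)) {
    perm <- sample.int(n)
    tr <- perm[seq_len(n_train)]
    te <- perm[(n_train + 1L):n]
    mu <- colMeans(x_all[tr, , drop = FALSE])
    sds <- apply(x_all[tr, , drop = FALSE], 2, sd)
    sds[sds == 0 | is.na(sds)] <- 1
    scaling <- list(mean = mu, sd = sds)
    xtr <- scale_inputs(x_all[tr, , drop = FALSE], scaling)
    xte <- scale_inputs(x_all[te, , drop = FALSE], scaling)

    net0 <- mlp_init(ncol(x_all), ncol(y_all), hidden = hidden,
                     n_relu = n_relu, dropout = dropout)
    fit <- mlp_train(net0, xtr, y_all[tr, , drop = FALSE], epochs = epochs,
                     batch_size = batch_size, lr = lr,
                     track_loss = track_loss)
    pred <- pmax(mlp_forward(fit$net, xte)$out, 0)
    truth <- y_all[te, , drop = FALSE]
    metrics[[fold]] <- tibble::tibble(
      fold = fold,
      fragment = sub("^frag_", "", target_cols),
      r2 = vapply(seq_along(target_cols), function(j) {
        if (var(truth[, j]) == 0 || var(pred[, j]) == 0) NA_real_
        else cor(pred[, j], truth[, j])^2
      }, numeric(1)),
      mae = colMeans(abs(pred - truth))
    )
    losses[[fold]] <- fit$losses
    if (fold == 1) first <- list(net = fit$net, scaling = scaling)
  }

  report <- structure(
    list(metrics = dplyr::bind_rows(metrics), losses = losses,
         n_train = n_train, n_test = n - n_train, cv_folds = cv_folds,
         epochs = epochs, seed = seed),
    class = "fragnet_report"
  )
  structure(
    list(net = first$net, catalog = sub("^frag_", "", target_cols),
         input_cols = input_cols, scaling = first$scaling, trained = TRUE,
         report = report,
         config = list(hidden = hidden, n_relu = n_relu, dropout = dropout,
                       lr = lr, optimizer = "adamax", loss = "mae",
                       seed = seed, epochs = epochs,
                       batch_size = batch_size)),
    class = "fragment_net"
  )
}

#' Predict fragment counts
#'
#' Runs the trained network on new compounds. Predictions are non-negative
#' decimals (clamped at zero, never rounded): they behave like expected
#' counts, and similarity metrics should be computed on the decimals, since
#' rounding to integers discards information and can corrupt matches.
#'
#' @param model A trained `fragment_net`.
#' @param data Modelling table from [prepare_model_data()] (targets
#'   optional).
#'
#' @return Tibble with `compound_id` and one `frag_<name>` column per
#'   catalog fragment.
#' @export
predict_fragments <- function(model, data) {
  stopifnot(inherits(model, "fragment_net"))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  missing_cols <- setdiff(model$input_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks model input column(s): ",
         paste(head(missing_cols, 5), collapse = ", "))
  }
  x <- as.matrix(data[model$input_cols])
  if (anyNA(x)) {
    stop("model inputs contain missing values; impute the fingerprint ",
         "panel first (impute_fingerprints())")
  }
  pred <- pmax(mlp_forward(model$net, scale_inputs(x, model$scaling))$out, 0)
  colnames(pred) <- paste0("frag_", model$catalog)
  dplyr::bind_cols(
    tibble::tibble(compound_id = data$compound_id),
    tibble::as_tibble(pred)
  )
}

#' Compare predicted and true fragment vectors
#'
#' Scores predictions against truth along the fragment axis, per compound:
#' the squared Pearson correlation between the two vectors and their mean
#' absolute error, computed on the decimal predictions (no rounding). A
#' zero-variance vector leaves `r2` undefined (`NA`); the MAE is always
#' returned.
#'
#' @param pred Tibble of predictions (`compound_id` + `frag_<name>`), or a
#'   bare numeric vector.
#' @param truth Tibble of true counts in the same layout, or a bare numeric
#'   vector of the same length as `pred`.
#'
#' @return Tibble with `compound_id` (when given tibbles), `r2`, `mae`, `n`.
#' @export
#'
#' @examples
#' evaluate_fragments(c(1.1, 0.2, 2.3), c(1, 0, 2))
evaluate_fragments <- function(pred, truth) {
  if (is.numeric(pred) && is.numeric(truth)) {
    stopifnot(length(pred) == length(truth))
    return(tibble::tibble(
      r2 = if (var(pred) == 0 || var(truth) == 0) NA_real_
           else cor(pred, truth)^2,
      mae = mean(abs(pred - truth)),
      n = length(pred)
    ))
  }
  frag_cols <- intersect(grep("^frag_", names(pred), value = TRUE),
                         grep("^frag_", names(truth), value = TRUE))
  if (length(frag_cols) == 0) stop("no shared frag_* columns to compare")
  joined <- dplyr::inner_join(
    dplyr::select(pred, "compound_id", dplyr::all_of(frag_cols)),
    dplyr::select(truth, "compound_id", dplyr::all_of(frag_cols)),
    by = "compound_id", suffix = c("_pred", "_true")
  )
  purrr::map_dfr(seq_len(nrow(joined)), function(i) {
    p <- as.numeric(joined[i, paste0(frag_cols, "_pred")])
    t_ <- as.numeric(joined[i, paste0(frag_cols, "_true")])
    dplyr::bind_cols(tibble::tibble(compound_id = joined$compound_id[i]),
                     evaluate_fragments(p, t_))
  })
}

#' @export
print.fragment_net <- function(x, ...) {
  cat("<fragment_net> ", if (isTRUE(x$trained)) "trained" else "untrained",
      "; ", x$config$n_relu, " ReLU layers x ", x$config$hidden,
      " units + dropout(", x$config$dropout, ") + exponential layer; ",
      length(x$catalog), " output fragments\n", sep = "")
  invisible(x)
}

#' @export
print.fragnet_report <- function(x, ...) {
  cat("<fragnet_report> ", x$cv_folds, " shuffle-split fold(s), ",
      x$epochs, " epochs, train/test = ", x$n_train, "/", x$n_test,
      ", seed ", x$seed, "\n", sep = "")
  summ <- x$metrics |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(mean_r2 = mean(.data$r2, na.rm = TRUE),
                     mean_mae = mean(.data$mae), .groups = "drop")
  print(summ)
  invisible(x)
}

#' Tidy and summarize fragment-model results
#'
#' `tidy()` returns the per-fold per-fragment test metrics of a trained
#' model; `glance()` a one-row summary.
#'
#' @param x A trained `fragment_net`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fragment_net <- function(x, ...) {
  if (is.null(x$report)) stop("model has no training report")
  x$report$metrics
}

#' @rdname tidy.fragment_net
#' @export
glance.fragment_net <- function(x, ...) {
  m <- x$report$metrics
  tibble::tibble(
    cv_folds = x$report$cv_folds, epochs = x$report$epochs,
    n_train = x$report$n_train, n_test = x$report$n_test,
    seed = x$report$seed,
    mean_test_r2 = mean(m$r2, na.rm = TRUE),
    mean_test_mae = mean(m$mae)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a read-across model
#'
#' @param x A `readacross_model`.
#' @param ... Unused.
#' @return Tibble of terms and estimates.
#' @export
tidy.readacross_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.readacross_model
#' @export
glance.readacross_model <- function(x, ...) {
  tibble::tibble(target = x$target,
                 predictors = paste(x$predictors, collapse = "+"),
                 n_train = x$n_train)
}
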