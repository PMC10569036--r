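#' Fit a read-across regression for one solvent
#'
#' Models the log K_SW of a target solvent as an ordinary-least-squares
#' multilinear function of three other solvents' log K_SW, fitted over the
#' complete-case rows of a reference database:
#' `K_target = c + a K_1 + b K_2 + d K_3`.
#'
#' @param db Wide reference database with `logK_<solvent>` columns.
#' @param target Target solvent name.
#' @param predictors Character vector of 3 distinct predictor solvents.
#'
#' @return Object of class `readacross_model`: list with `target`,
#'   `predictors`, `coefficients` (named: `(Intercept)` then the predictor
#'   weights) and `n_train`.
#' @export
#'
#' @examples
#' db <- tibble::tibble(logK_a = rnorm(20), logK_b = rnorm(20),
#'                      logK_c = rnorm(20))
#' db$logK_t <- 2 * db$logK_a - db$logK_b + 0.5 * db$logK_c + 1
#' fit_readacross(db, "t", c("a", "b", "c"))$coefficients
fit_readacross <- function(db, target, predictors) {
  stopifnot(length(predictors) == 3, !target %in% predictors,
            !anyDuplicated(predictors))
  cols <- paste0("logK_", c(target, predictors))
  missing_cols <- setdiff(cols, names(db))
  if (length(missing_cols) > 0) {
    stop("reference database lacks solvent column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- db[cols]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 4) {
    stop("read-across fit needs at least 4 complete-case compounds; got ",
         nrow(dat))
  }
  x <- cbind(`(Intercept)` = 1, as.matrix(dat[, -1]))
  y <- dat[[1]]
  fit <- stats::lm.fit(x, y)
  if (fit$rank < 4L) {
    cond <- structure(
      class = c("partprint_rank_deficient", "error", "condition"),
      list(message = paste0("rank-deficient read-across design for target '",
                            target, "' with predictors ",
                            paste(predictors, collapse = ", ")),
           call = sys.call())
    )
    stop(cond)
  }
  structure(
    list(target = target, predictors = predictors,
         coefficients = setNames(fit$coefficients,
                                 c("(Intercept)", predictors)),
         n_train = nrow(dat)),
    class = "readacross_model"
  )
}

#' @export
print.readacross_model <- function(x, ...) {
  cat("<readacross_model> logK_", x$target, " ~ ",
      paste0("logK_", x$predictors, collapse = " + "),
      "  (n = ", x$n_train, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a read-across model
#'
#' @param object A `readacross_model`.
#' @param newdata Named numeric vector (or single-row data frame) holding the
#'   predictor solvents' log K_SW values.
#' @param ... Unused.
#' @return Predicted target log K_SW (numeric scalar).
#' @export
predict.readacross_model <- function(object, newdata, ...) {
  v <- unlist(newdata)[object$predictors]
  if (anyNA(v)) stop("missing predictor value(s) for read-across prediction")
  unname(object$coefficients[1] + sum(object$coefficients[-1] * v))
}

#' Impute missing fingerprint entries by randomized read-across
#'
#' For each missing solvent of each compound, repeatedly (`n_iter` times)
#' samples three of the compound's observed solvents, fits a read-across
#' regression for the missing solvent on the reference database, predicts
#' from the compound's observed values, and averages the predictions.
#' Triplets are sampled without replacement within an iteration and
#' independently across iterations; rank-deficient fits are discarded and
#' resampled (up to `10 * n_iter` attempts). Compounds with fewer than 3
#' observed solvents cannot be imputed and are left untouched with a
#' warning: the downstream model requires a complete panel, so they are not
#' usable as model input.
#'
#' Imputed entries have `imputed = TRUE`, `n_used = 0`, and `sd` set to the
#' spread of the per-iteration predictions (informational).
#'
#' @param fp Fingerprint tibble (long; `NA` values mark missing entries).
#' @param db Wide reference database with `logK_<solvent>` columns.
#' @param n_iter Number of random triplet iterations per missing entry.
#' @param seed Optional integer seed for reproducible triplet sampling.
#'
#' @return Fingerprint tibble with missing entries filled where possible.
#' @export
impute_fingerprints <- function(fp, db, n_iter = 100, seed = NULL) {
  stopifnot(n_iter >= 1)
  if (any(fp$standardized)) {
    stop("impute_fingerprints() expects raw (unstandardized) fingerprints")
  }
  if (!is.null(seed)) set.seed(seed)

  cache <- new.env(parent = emptyenv())
  fit_cached <- function(target, triplet) {
    key <- paste(target, paste(sort(triplet), collapse = "|"), sep = "~")
    if (!is.null(cache[[key]])) return(cache[[key]])
    model <- tryCatch(fit_readacross(db, target, triplet),
                      partprint_rank_deficient = function(e) NULL)
    cache[[key]] <- if (is.null(model)) list(NULL) else model
    cache[[key]]
  }

  out <- fp
  compounds <- unique(fp$compound_id)
  skipped <- character()
  for (cid in compounds) {
    idx <- which(out$compound_id == cid)
    values <- setNames(out$value[idx], out$solvent[idx])
    observed <- names(values)[!is.na(values)]
    missing <- names(values)[is.na(values)]
    if (length(missing) == 0) next
    if (length(observed) < 3) {
      skipped <- c(skipped, cid)
      next
    }
    for (tgt in missing) {
      preds <- numeric(0)
      attempts <- 0L
      while (length(preds) < n_iter && attempts < 10L * n_iter) {
        attempts <- attempts + 1L
        triplet <- sample(observed, 3)
        model <- fit_cached(tgt, triplet)
        if (is.null(model[[1]]) && length(model) == 1) next
        preds <- c(preds, predict(model, values[observed]))
      }
      if (length(preds) < n_iter) {
        stop("could not assemble ", n_iter,
             " valid read-across fits for compound '", cid,
             "', solvent '", tgt, "' (reference database too collinear)")
      }
      j <- idx[out$solvent[idx] == tgt]
      out$value[j] <- mean(preds)
      out$imputed[j] <- TRUE
      if ("sd" %in% names(out)) out$sd[j] <- sd(preds)
      if ("n_used" %in% names(out)) out$n_used[j] <- 0L
    }
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " compound(s) with fewer than 3 observed ",
            "solvents left unimputed (complete panels are required for ",
            "model input): ", paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  out
}
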