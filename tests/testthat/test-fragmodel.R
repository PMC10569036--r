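# Small architectures are used here to keep unit tests fast; the full-width
# network is exercised in the acceptance suite.

test_that("the network architecture matches its contract", {
  model <- build_fragment_net(33, default_fragments(), seed = 1)
  layers <- net_layers(model)
  expect_equal(nrow(layers), 14) # input + 10 ReLU + dropout + exp + output
  expect_equal(sum(layers$activation == "relu"), 10)
  expect_equal(sum(layers$type == "dropout"), 1)
  expect_equal(sum(layers$activation == "exponential"), 1)
  expect_equal(layers$activation[nrow(layers)], "linear")
  expect_equal(layers$units[nrow(layers)], length(default_fragments()))
  expect_true(all(layers$units[layers$type == "dense" &
                                 layers$activation != "linear"] == 500))
  expect_equal(model$config$optimizer, "adamax")
  expect_equal(model$config$lr, 0.001)
  expect_equal(model$config$loss, "mae")
})

test_that("weight initialization is seeded and the forward pass is finite", {
  a <- build_fragment_net(10, c("x", "y"), hidden = 16, n_relu = 3, seed = 7)
  b <- build_fragment_net(10, c("x", "y"), hidden = 16, n_relu = 3, seed = 7)
  expect_identical(a$net$w, b$net$w)
  zero <- matrix(0, nrow = 1, ncol = 10)
  out <- partprint:::mlp_forward(a$net, zero)$out
  expect_equal(length(out), 2)
  expect_true(all(is.finite(out)))
})

test_that("evaluation metrics behave on the fragment axis", {
  truth <- c(1, 0, 2, 0, 3)
  expect_equal(evaluate_fragments(truth, truth)$r2, 1)
  expect_equal(evaluate_fragments(truth, truth)$mae, 0)
  off <- evaluate_fragments(truth + 0.5, truth)
  expect_equal(off$mae, 0.5)
  expect_equal(off$r2, 1)
  # a flat vector leaves r2 undefined but still yields the MAE
  flat <- evaluate_fragments(rep(1, 5), truth)
  expect_true(is.na(flat$r2))
  expect_equal(flat$mae, mean(abs(1 - truth)))
})

test_that("1,4-dichlorobenzene-style truth vectors score as expected", {
  catalog <- default_fragments()
  truth <- setNames(rep(0, length(catalog)), catalog)
  truth["benzene"] <- 1
  truth["halogen"] <- 2
  pred <- truth + c(0.1, -0.05, 0.2, 0, 0.1, 0, 0, 0.05, -0.2, 0, 0.1, 0)
  res <- evaluate_fragments(unname(pred), unname(truth))
  expect_gt(res$r2, 0.9)
  expect_lt(res$mae, 0.2)
})

test_that("metrics agree with an independent straight-line-fit oracle", {
  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- 0.7 * x + rnorm(12, sd = 0.5)
    res <- evaluate_fragments(x, y)
    fit <- summary(lm(y ~ x))
    expect_equal(res$r2, fit$r.squared, tolerance = 1e-8)
    expect_equal(res$mae, mean(abs(x - y)), tolerance = 1e-12)
  }
})

small_training_run <- function(epochs = 25) {
  panel <- cached_panel("model_small",
                        sim_config(n_compounds = 150, seed = 17))
  dat <- panel_model_data(panel)
  model <- train_fragment_net(dat, epochs = epochs, cv_folds = 1,
                              batch_size = 32, hidden = 32, n_relu = 3,
                              dropout = 0.1, seed = 3)
  list(panel = panel, dat = dat, model = model)
}

test_that("training learns, reports, and predicts deterministically", {
  run <- small_training_run()
  model <- run$model
  losses <- model$report$losses[[1]]
  expect_equal(length(losses), 25)
  expect_lt(losses[25], losses[1]) # optimizer reduces the training MAE
  expect_equal(model$report$n_train, 120)
  expect_equal(model$report$n_test, 30)

  pred1 <- predict_fragments(model, run$dat)
  pred2 <- predict_fragments(model, run$dat)
  expect_identical(pred1, pred2)
  frag_cols <- grep("^frag_", names(pred1), value = TRUE)
  expect_true(all(as.matrix(pred1[frag_cols]) >= 0))
  expect_equal(length(frag_cols), length(model$catalog))

  # tidy/glance accessors
  expect_s3_class(tidy(model), "tbl_df")
  expect_equal(nrow(tidy(model)), length(model$catalog))
  expect_equal(glance(model)$epochs, 25)
})

test_that("incomplete fingerprints are rejected with a pointer to imputation", {
  run <- small_training_run()
  dat <- run$dat
  dat$fp_octanol[3] <- NA
  expect_error(predict_fragments(run$model, dat), "impute")

  panel <- run$panel
  fp <- truth_fp(panel, "CMP0001")
  fp$value[1] <- NA
  fp_std <- standardize_fingerprints(fp)
  expect_error(
    prepare_model_data(fp_std, panel$reference_db,
                       panel = panel$config$solvents),
    "impute"
  )
  # raw fingerprints are rejected before modelling
  expect_error(prepare_model_data(truth_fp(panel, "CMP0001"),
                                  panel$reference_db), "standardize")
})

test_that("predictions are invariant to raw-fingerprint offsets", {
  run <- small_training_run()
  panel <- run$panel
  ids <- sprintf("CMP%04d", 1:5)
  raw <- truth_fp(panel, ids)
  shifted <- dplyr::mutate(raw, value = value + 0.9)
  d1 <- prepare_model_data(standardize_fingerprints(raw),
                           panel$reference_db,
                           priors = fragment_priors(panel$isomers),
                           panel = panel$config$solvents)
  d2 <- prepare_model_data(standardize_fingerprints(shifted),
                           panel$reference_db,
                           priors = fragment_priors(panel$isomers),
                           panel = panel$config$solvents)
  expect_equal(predict_fragments(run$model, d1),
               predict_fragments(run$model, d2), tolerance = 1e-12)
})

test_that("a saved model reloads and reproduces its predictions", {
  run <- small_training_run()
  dir <- withr::local_tempdir()
  save_fragment_net(run$model, file.path(dir, "model"))
  back <- load_fragment_net(file.path(dir, "model"))
  expect_equal(predict_fragments(back, run$dat),
               predict_fragments(run$model, run$dat), tolerance = 1e-12)
  expect_equal(back$catalog, run$model$catalog)
})
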