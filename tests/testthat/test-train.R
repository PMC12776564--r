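# small hand-built dataset helper: random inputs with geometric targets
tiny_dataset <- function(n, g = 16L, seed = 1) {
  with_seed(seed, {
    inputs <- array(runif(g * g * n), c(g, g, n))
    lung <- array(0, c(g, g, n)); heart <- array(0, c(g, g, n))
    for (i in seq_len(n)) {
      lung[2:6, 2:6, i] <- 1
      heart[(g - 5):(g - 2), (g - 5):(g - 2), i] <- 1
    }
    structure(list(inputs = inputs, lung_targets = lung, heart_targets = heart,
                   provenance = data.frame(sample = seq_len(n)),
                   meta = list(n = n, seed = seed, grid = g,
                               continuous_targets = FALSE)),
              class = "eit_dataset")
  })
}

test_that("a high-capacity model overfits a repeated sample to near-zero loss", {
  ds <- tiny_dataset(2)
  ds$inputs[, , 2] <- ds$inputs[, , 1]     # identical samples
  sp <- structure(list(train = 1L, validation = 2L), class = "dataset_split")
  spec <- model_spec(input_size = 16, depth = 2, base_channels = 8)
  m <- build_semi_siamese(spec, seed = 3)
  cfg <- training_config(epochs = 120, batch_size = 1, patience = Inf, seed = 2)
  fit <- train_model(m, ds, sp, cfg, loss_weights(1, 1))
  expect_lt(min(fit$history$train_loss), 0.01)
})

test_that("training is reproducible and records a complete history", {
  ds <- tiny_dataset(8)
  sp <- split_dataset(8, 0.75, seed = 1)
  spec <- model_spec(input_size = 16, depth = 2, base_channels = 4)
  cfg <- training_config(epochs = 4, batch_size = 4, patience = Inf, seed = 7)
  f1 <- train_model(build_semi_siamese(spec, seed = 5), ds, sp, cfg, loss_weights(1, 2))
  f2 <- train_model(build_semi_siamese(spec, seed = 5), ds, sp, cfg, loss_weights(1, 2))
  expect_identical(tail(f1$history$val_loss, 1), tail(f2$history$val_loss, 1))
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$history$epoch, 1:4)
  expect_true(all(is.finite(unlist(f1$history))))
  expect_s3_class(f1, "eit_fit")
})

test_that("grid search produces one record per Wc plus a labelled baseline", {
  ds <- tiny_dataset(8)
  sp <- split_dataset(8, 0.75, seed = 2)
  te <- tiny_dataset(4, seed = 9)
  spec <- model_spec(input_size = 16, depth = 2, base_channels = 4)
  cfg <- training_config(epochs = 2, batch_size = 4, patience = Inf, seed = 1,
                         wc_grid = c(1.0, 1.5))
  g <- grid_search_wc(ds, sp, te, cfg, spec)
  expect_equal(nrow(g), 3)
  expect_equal(g$wc, c("1", "1.5", "baseline"))
  expect_true(all(is.finite(g$heart_dsc)))
  base <- g[g$wc == "baseline", ]
  sm <- g[g$wc != "baseline", ]
  expect_equal(sm$heart_dsc_improvement, sm$heart_dsc - base$heart_dsc)
  expect_equal(sm$heart_mae_improvement, base$heart_mae - sm$heart_mae)
  expect_true(all(is.na(g$heart_dsc_improvement[g$wc == "baseline"])))
  # single-point grid still works
  cfg1 <- training_config(epochs = 1, batch_size = 4, seed = 1, wc_grid = 1.8)
  g1 <- grid_search_wc(ds, sp, te, cfg1, spec)
  expect_equal(g1$wc, c("1.8", "baseline"))
  # CSV export round-trips the table
  p <- tempfile(fileext = ".csv")
  write_metrics_csv(g, p)
  expect_equal(nrow(utils::read.csv(p)), 3)
  unlink(p)
})

test_that("divergent and degenerate configurations error clearly", {
  ds <- tiny_dataset(4)
  sp <- structure(list(train = 1:3, validation = integer(0)),
                  class = "dataset_split")
  spec <- model_spec(input_size = 16, depth = 2, base_channels = 4)
  expect_error(train_model(build_semi_siamese(spec), ds, sp,
                           training_config(epochs = 1)),
               "non-empty")
  expect_error(training_config(eps = 0.7), "eps")
  expect_error(training_config(wc_grid = c(1, -1)), "wc_grid")
})
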