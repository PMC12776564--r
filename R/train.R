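#' Training configuration
#'
#' Optimization hyperparameters for [train_model()]: Adam with the
#' stated learning rate, mini-batch size, epoch budget and early
#' stopping on validation loss. The `wc_grid` is the set of heart/lung
#' weight ratios explored by [grid_search_wc()].
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 32).
#' @param epochs maximum epochs (default 60).
#' @param patience early-stopping patience in epochs (default 10);
#'   `Inf` disables early stopping.
#' @param eps clipping constant for the BCE logs, in (0, 0.5).
#' @param seed master seed; fans out to shuffling and initialization.
#' @param wc_grid weight-ratio grid (default `c(1.0, 1.5, 1.8, 2.0)`).
#' @param lr_schedule `"constant"`, or `"cosine"` for a half-cosine decay
#'   of the learning rate from its initial value to zero over `epochs`.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 32L,
                            epochs = 60L, patience = 10L, eps = 1e-7,
                            seed = 1L, wc_grid = c(1.0, 1.5, 1.8, 2.0),
                            lr_schedule = c("constant", "cosine")) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            eps > 0, eps < 0.5, all(wc_grid > 0), length(wc_grid) >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience, eps = eps,
                 seed = as.integer(seed), wc_grid = wc_grid,
                 lr_schedule = match.arg(lr_schedule)),
            class = "training_config")
}

epoch_lr <- function(config, ep) {
  if (identical(config$lr_schedule, "cosine"))
    config$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
  else config$learning_rate
}

dataset_tensors <- function(dataset, idx) {
  g <- dataset$meta$grid
  list(x = matrix(dataset$inputs[, , idx], ncol = 1L),
       lung = matrix(dataset$lung_targets[, , idx], ncol = 1L),
       heart = matrix(dataset$heart_targets[, , idx], ncol = 1L),
       n = length(idx), px = g * g)
}

# loss + logit gradients for one batch, shared by both architectures
batch_loss_grad <- function(model, logits, lung_t, heart_t, weights, eps) {
  npx <- length(lung_t)
  if (inherits(model, "classical_unet")) {
    lg <- logits$dec_
    pl <- sigmoid(lg[, 1L, drop = FALSE]); ph <- sigmoid(lg[, 2L, drop = FALSE])
    dlg <- cbind(weights$w_lung * (pl - lung_t),
                 weights$w_heart * (ph - heart_t)) / npx
    list(loss = total_loss(pl, lung_t, ph, heart_t, weights, eps),
         dlogits = list(dec_ = dlg))
  } else {
    pl <- sigmoid(logits$lung_); ph <- sigmoid(logits$heart_)
    list(loss = total_loss(pl, lung_t, ph, heart_t, weights, eps),
         dlogits = list(lung_ = weights$w_lung * (pl - lung_t) / npx,
                        heart_ = weights$w_heart * (ph - heart_t) / npx))
  }
}

eval_tensors <- function(model, tens, weights, eps, threshold = 0.5) {
  logits <- nn_forward(model, tens$x, tens$n)$logits
  bl <- batch_loss_grad(model, logits, tens$lung, tens$heart, weights, eps)
  pr <- nn_predict(model, tens$x, tens$n)
  per_sample <- function(p, t, f) {
    pm <- matrix(p, tens$px); tm <- matrix(t, tens$px)
    mean(vapply(seq_len(tens$n), function(i) f(pm[, i], tm[, i]), 0))
  }
  list(loss = bl$loss,
       lung_dsc = per_sample(pr$lung_, tens$lung,
                             function(p, t) dice(binarize(p, threshold), t)),
       heart_dsc = per_sample(pr$heart_, tens$heart,
                              function(p, t) dice(binarize(p, threshold), t)),
       lung_mae = per_sample(pr$lung_, tens$lung, mae),
       heart_mae = per_sample(pr$heart_, tens$heart, mae))
}

#' Train a U-Net on a simulated EIT dataset
#'
#' Mini-batch Adam optimization of the multi-weighted BCE objective.
#' Per-epoch validation loss and per-task Dice/MAE are recorded; the
#' parameters with the best validation loss are retained. Fully
#' deterministic given `config$seed` (shuffling) and the model's
#' initialization seed.
#'
#' @param model an `eit_unet` from [build_semi_siamese()] or
#'   [build_baseline()].
#' @param dataset an `eit_dataset`.
#' @param split a [split_dataset()] result; train and validation must be
#'   non-empty.
#' @param config a [training_config()].
#' @param weights a [loss_weights()].
#' @param verbose print one line per epoch.
#' @return object of class `eit_fit`: list with the trained `model`,
#'   `history` (one row per epoch), `best_epoch`, `weights`, `config`.
#' @export
train_model <- function(model, dataset, split, config = training_config(),
                        weights = loss_weights(), verbose = FALSE) {
  stopifnot(inherits(model, "eit_unet"), inherits(dataset, "eit_dataset"),
            inherits(split, "dataset_split"), inherits(config, "training_config"),
            inherits(weights, "loss_weights"))
  if (length(split$train) < 1 || length(split$validation) < 1)
    stop("train and validation sets must be non-empty")
  tr <- dataset_tensors(dataset, split$train)
  va <- dataset_tensors(dataset, split$validation)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- vector("list", config$epochs)
  stale <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, ep), sample.int(tr$n))
    lr_ep <- epoch_lr(config, ep)
    ep_loss <- 0
    for (start in seq(1L, tr$n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, tr$n)]
      rows <- as.vector(outer(seq_len(tr$px), (idx - 1L) * tr$px, `+`))
      x <- tr$x[rows, , drop = FALSE]
      lt <- tr$lung[rows, , drop = FALSE]
      ht <- tr$heart[rows, , drop = FALSE]
      fw <- nn_forward(model, x, length(idx), want_cache = TRUE)
      bl <- batch_loss_grad(model, fw$logits, lt, ht, weights, config$eps)
      if (!is.finite(bl$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      grads <- nn_backward(model, x, fw, bl$dlogits)
      upd <- adam_step(model$params, grads, state, lr = lr_ep)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl$loss * length(idx)
    }
    vm <- eval_tensors(model, va, weights, config$eps)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / tr$n,
                             val_loss = vm$loss,
                             val_lung_dsc = vm$lung_dsc,
                             val_heart_dsc = vm$heart_dsc,
                             val_lung_mae = vm$lung_mae,
                             val_heart_mae = vm$heart_mae)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  heart DSC %.4f",
                      ep, ep_loss / tr$n, vm$loss, vm$heart_dsc))
    if (vm$loss < best$loss) {
      best <- list(loss = vm$loss, params = model$params, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best$epoch, weights = weights, config = config),
            class = "eit_fit")
}

#' @export
print.eit_fit <- function(x, ...) {
  h <- x$history
  cat("Trained ", if (inherits(x$model, "semi_siamese_unet")) "semi-Siamese U-Net"
      else "classical U-Net", " (Wc = ", format(x$weights$wc), ")\n",
      "  epochs run ", nrow(h), ", best epoch ", x$best_epoch,
      ", best val loss ", format(min(h$val_loss), digits = 5), "\n", sep = "")
  invisible(x)
}

#' @export
summary.eit_fit <- function(object, ...) {
  h <- object$history
  b <- h[h$epoch == object$best_epoch, ]
  cat("Validation metrics at the retained (best-loss) epoch:\n")
  cat(sprintf("  heart DSC %.4f  MAE %.4f %%   lung DSC %.4f  MAE %.4f %%\n",
              b$val_heart_dsc, b$val_heart_mae, b$val_lung_dsc, b$val_lung_mae))
  invisible(b)
}

#' @export
predict.eit_fit <- function(object, images, ...) predict(object$model, images, ...)

#' Plot training history
#'
#' Validation loss and per-task validation Dice against the epoch index.
#'
#' @param x an `eit_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eit_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$val_loss, type = "l", xlab = "epoch",
                 ylab = "validation loss", ...)
  graphics::lines(h$epoch, h$train_loss, lty = 2)
  graphics::legend("topright", c("validation", "training"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$val_heart_dsc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "validation DSC", ...)
  graphics::lines(h$epoch, h$val_lung_dsc, lty = 2)
  graphics::legend("bottomright", c("heart", "lung"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Grid search over the heart/lung weight ratio
#'
#' Trains one semi-Siamese model per Wc in the grid (W_lung fixed at 1,
#' W_heart = Wc) plus the classical U-Net baseline at unit weights, each
#' from an independently derived seed, and evaluates every run on the
#' same held-out test set. Relative-improvement columns compare each
#' semi-Siamese run against the baseline.
#'
#' @param dataset training/validation `eit_dataset`.
#' @param split a [split_dataset()] result.
#' @param test independent test `eit_dataset`.
#' @param config a [training_config()]; `config$wc_grid` defines the
#'   grid.
#' @param spec a [model_spec()] shared by all runs.
#' @param threshold binarization threshold for Dice.
#' @param paired_seeds if FALSE (default) every grid point trains from an
#'   independently derived seed; if TRUE all grid points share one
#'   initialization and shuffling seed, so the runs differ only in their
#'   loss weights. Pairing removes optimization noise from the
#'   between-weight contrast and is the recommended design when the
#'   epoch budget is small relative to convergence.
#' @param verbose print progress.
#' @return object of class `wc_grid`: data frame with one row per run
#'   (`wc` = "baseline" for the classical U-Net) and columns
#'   `heart_dsc`, `heart_mae`, `lung_dsc`, `lung_mae`,
#'   `heart_dsc_improvement`, `heart_mae_improvement` (percent /
#'   percentage points), plus the fitted models in
#'   `attr(, "fits")`.
#' @export
grid_search_wc <- function(dataset, split, test, config = training_config(),
                           spec = model_spec(), threshold = 0.5,
                           paired_seeds = FALSE, verbose = FALSE) {
  runs <- c(as.list(config$wc_grid), list("baseline"))
  fits <- vector("list", length(runs))
  rows <- vector("list", length(runs))
  base_rec <- NULL
  for (k in seq_along(runs)) {
    wc <- runs[[k]]
    run_seed <- if (paired_seeds) derive_seed(config$seed, 100L)
                else derive_seed(config$seed, 100L + k)
    cfg <- config; cfg$seed <- run_seed
    if (identical(wc, "baseline")) {
      model <- build_baseline(spec, seed = run_seed)
      w <- loss_weights(1, 1)
    } else {
      model <- build_semi_siamese(spec, seed = run_seed)
      w <- loss_weights(1, wc)
    }
    if (verbose) message("training ", if (identical(wc, "baseline")) "baseline"
                         else paste0("Wc = ", wc))
    fit <- train_model(model, dataset, split, cfg, w)
    rec <- evaluate(fit, test, threshold)
    fits[[k]] <- fit
    rows[[k]] <- data.frame(
      wc = if (identical(wc, "baseline")) "baseline" else format(wc),
      heart_dsc = rec$heart_dsc, heart_mae = rec$heart_mae,
      lung_dsc = rec$lung_dsc, lung_mae = rec$lung_mae,
      stringsAsFactors = FALSE)
    if (identical(wc, "baseline")) base_rec <- rec
  }
  out <- do.call(rbind, rows)
  out$heart_dsc_improvement <- relative_improvement(out$heart_dsc,
                                                    base_rec$heart_dsc,
                                                    "higher_better")
  out$heart_mae_improvement <- relative_improvement(out$heart_mae,
                                                    base_rec$heart_mae,
                                                    "lower_better")
  out$heart_dsc_improvement[out$wc == "baseline"] <- NA
  out$heart_mae_improvement[out$wc == "baseline"] <- NA
  attr(out, "fits") <- fits
  class(out) <- c("wc_grid", "data.frame")
  out
}

#' Export a grid-search table to CSV
#'
#' @param grid a `wc_grid`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Plot Dice and MAE against the weight ratio
#'
#' The trend curves: test-set heart/lung Dice (left axis) and MAE
#' (right panel) as functions of Wc, with the baseline as a horizontal
#' reference line.
#'
#' @param x a `wc_grid`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wc_grid <- function(x, ...) {
  d <- as.data.frame(x)
  sm <- d[d$wc != "baseline", ]
  bs <- d[d$wc == "baseline", ]
  wc <- as.numeric(sm$wc)
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(wc, sm$heart_dsc, type = "b", xlab = "Wc",
                 ylab = "test DSC (%)", ylim = range(c(sm$heart_dsc, sm$lung_dsc,
                                                       bs$heart_dsc)), ...)
  graphics::lines(wc, sm$lung_dsc, type = "b", lty = 2)
  graphics::abline(h = bs$heart_dsc, col = "grey50", lty = 3)
  graphics::legend("bottomright", c("heart", "lung", "baseline heart"),
                   lty = c(1, 2, 3), bty = "n")
  graphics::plot(wc, sm$heart_mae, type = "b", xlab = "Wc",
                 ylab = "test MAE (%)", ylim = range(c(sm$heart_mae, sm$lung_mae,
                                                       bs$heart_mae)), ...)
  graphics::lines(wc, sm$lung_mae, type = "b", lty = 2)
  graphics::abline(h = bs$heart_mae, col = "grey50", lty = 3)
  invisible(x)
}
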