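#' Threshold a probability map into a binary mask
#'
#' Pixel = 1 iff value >= threshold. Idempotent on binary masks.
#'
#' @param prob_map numeric matrix/array of values in \[0, 1\].
#' @param threshold scalar in (0, 1), default 0.5.
#' @return 0/1 object of the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (prob_map >= threshold) * 1
}

#' Dice similarity coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|). Two empty masks agree perfectly on absence
#' and score 1.
#'
#' @param mask_a,mask_b binary masks of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("mask shapes differ")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a * mask_b) / (sa + sb)
}

#' Mean absolute error between two maps, in percent
#'
#' 100 * mean(|pred - target|) over all pixels.
#'
#' @param pred_map,target_map numeric maps of identical shape with
#'   values in \[0, 1\].
#' @return non-negative scalar (percent).
#' @export
mae <- function(pred_map, target_map) {
  if (length(pred_map) != length(target_map)) stop("map shapes differ")
  100 * mean(abs(pred_map - target_map))
}

#' Relative improvement over a baseline metric
#'
#' For higher-is-better metrics (Dice) the improvement is
#' model - baseline; for lower-is-better metrics (MAE) it is
#' baseline - model. Expressed in the metric's own units (percentage
#' points here).
#'
#' @param model_value,baseline_value metric values.
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @return signed improvement.
#' @export
relative_improvement <- function(model_value, baseline_value,
                                 orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (orientation == "higher_better") model_value - baseline_value
  else baseline_value - model_value
}

#' Evaluate a model on a test dataset
#'
#' Computes, separately for the heart and lung tasks, the mean
#' per-sample Dice coefficient (on maps binarized at `threshold`,
#' reported in percent) and the mean per-sample MAE (on the continuous
#' probability maps, percent). Aggregation is per-sample-then-mean, the
#' standard segmentation convention.
#'
#' @param model a trained `eit_unet` (or an `eit_fit`), or a function
#'   mapping the input array to `list(lung = , heart = )` probability
#'   arrays (useful for oracle models in consistency checks).
#' @param test an `eit_dataset`.
#' @param threshold binarization threshold.
#' @return object of class `metrics_record`: list with `lung_dsc`,
#'   `heart_dsc`, `lung_mae`, `heart_mae` (all percent) and `n`.
#' @export
evaluate <- function(model, test, threshold = 0.5) {
  if (inherits(model, "eit_fit")) model <- model$model
  stopifnot(inherits(model, "eit_unet") || is.function(model),
            inherits(test, "eit_dataset"))
  n <- test$meta$n
  if (n < 1) stop("empty test set")
  pr <- if (is.function(model)) model(test$inputs) else predict(model, test$inputs)
  ld <- hd <- lm_ <- hm <- numeric(n)
  for (i in seq_len(n)) {
    ld[i] <- dice(binarize(pr$lung[, , i], threshold), test$lung_targets[, , i])
    hd[i] <- dice(binarize(pr$heart[, , i], threshold), test$heart_targets[, , i])
    lm_[i] <- mae(pr$lung[, , i], test$lung_targets[, , i])
    hm[i] <- mae(pr$heart[, , i], test$heart_targets[, , i])
  }
  structure(list(lung_dsc = 100 * mean(ld), heart_dsc = 100 * mean(hd),
                 lung_mae = mean(lm_), heart_mae = mean(hm), n = n,
                 threshold = threshold),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("heart: DSC %6.2f %%  MAE %7.4f %%   lung: DSC %6.2f %%  MAE %7.4f %%  (n = %d)\n",
              x$heart_dsc, x$heart_mae, x$lung_dsc, x$lung_mae, x$n))
  invisible(x)
}
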