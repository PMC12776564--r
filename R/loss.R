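#' Numerically stable logistic sigmoid
#'
#' S(x) = 1 / (1 + exp(-x)), evaluated without overflow for large |x|.
#'
#' @param x numeric vector/array of pre-activations.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Binary cross-entropy between predicted probabilities and targets
#'
#' Mean over all pixels of -(t * log(p) + (1 - t) * log(1 - p)), with
#' predictions clipped to \[eps, 1 - eps\] so the logs stay finite.
#'
#' @param predictions probabilities in (0, 1), any shape.
#' @param targets ground truth in \[0, 1\], same shape.
#' @param eps clipping constant inside the logs (default 1e-7).
#' @return non-negative scalar.
#' @export
bce <- function(predictions, targets, eps = 1e-7) {
  if (length(predictions) != length(targets))
    stop("predictions and targets have different shapes")
  stopifnot(eps > 0, eps < 0.5)
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Loss weights for the multi-weighted objective
#'
#' Holds the lung and heart weights of the total loss; the derived ratio
#' Wc = W_heart / W_lung is the single hyperparameter varied in the grid
#' search (with W_lung fixed at 1).
#'
#' @param w_lung,w_heart non-negative weights, not both zero.
#' @return object of class `loss_weights` with fields `w_lung`,
#'   `w_heart`, `wc`.
#' @export
loss_weights <- function(w_lung = 1, w_heart = 1) {
  stopifnot(w_lung >= 0, w_heart >= 0, w_lung + w_heart > 0)
  structure(list(w_lung = w_lung, w_heart = w_heart,
                 wc = if (w_lung > 0) w_heart / w_lung else Inf),
            class = "loss_weights")
}

#' Multi-weighted total loss
#'
#' The training objective: W_lung * BCE(lung) + W_heart * BCE(heart).
#' Raising W_heart relative to W_lung (Wc > 1) penalizes heart
#' reconstruction errors more rigorously, which is the mechanism that
#' improves heart-image separation.
#'
#' @param lung_pred,heart_pred probability maps in (0, 1).
#' @param lung_target,heart_target target maps in \[0, 1\].
#' @param weights a [loss_weights()].
#' @param eps clipping constant passed to [bce()].
#' @return scalar loss.
#' @export
total_loss <- function(lung_pred, lung_target, heart_pred, heart_target,
                       weights = loss_weights(), eps = 1e-7) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$w_lung * bce(lung_pred, lung_target, eps) +
    weights$w_heart * bce(heart_pred, heart_target, eps)
}
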