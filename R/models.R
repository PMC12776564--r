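#' Model specification for the U-Net architectures
#'
#' Describes the shared hyperparameters of the semi-Siamese and the
#' classical U-Net: input grid side, encoder depth (number of resolution
#' levels including the bottleneck), base channel count at full
#' resolution, and channel growth factor per level. The input side must
#' be divisible by 2^(depth-1) so the pooling pyramid closes.
#'
#' @param input_size image side in pixels (default 32).
#' @param depth number of resolution levels (default 4: three 2x
#'   downsamplings to a 4x4 bottleneck for 32x32 inputs).
#' @param base_channels channels at the first level (default 16).
#' @param growth channel multiplication per level (default 2).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(input_size = 32L, depth = 4L, base_channels = 16L,
                       growth = 2L) {
  stopifnot(depth >= 2, base_channels >= 1, growth >= 1,
            input_size %% (2^(depth - 1)) == 0)
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 growth = as.integer(growth)),
            class = "model_spec")
}

spec_channels <- function(spec) spec$base_channels * spec$growth^(0:(spec$depth - 1))

init_encoder <- function(spec) {
  ch <- spec_channels(spec)
  params <- list()
  cin <- 1L
  for (l in seq_len(spec$depth)) {
    params[[sprintf("enc%d_c1", l)]] <- conv_init(cin, ch[l])
    params[[sprintf("enc%d_c2", l)]] <- conv_init(ch[l], ch[l])
    cin <- ch[l]
  }
  params
}

init_decoder <- function(spec, prefix, out_channels = 1L) {
  ch <- spec_channels(spec)
  params <- list()
  for (l in rev(seq_len(spec$depth - 1L))) {
    params[[sprintf("%sd%d_up", prefix, l)]] <- conv_init(ch[l + 1L], ch[l])
    params[[sprintf("%sd%d_c1", prefix, l)]] <- conv_init(2L * ch[l], ch[l])
    params[[sprintf("%sd%d_c2", prefix, l)]] <- conv_init(ch[l], ch[l])
  }
  params[[paste0(prefix, "head")]] <- conv_init(ch[1L], out_channels, ksize = 1L)
  params
}

#' Build the semi-Siamese U-Net
#'
#' One shared convolutional encoder feeding two structurally identical,
#' independently parameterized decoders (lung and heart), each receiving
#' skip connections from every encoder level and ending in a 1-channel
#' sigmoid head. The encoder parameters exist exactly once and are used
#' by both pathways; the two decoders share nothing.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the fan-in weight initialization.
#' @return object of class `c("semi_siamese_unet", "eit_unet")`.
#' @export
build_semi_siamese <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(seed, c(init_encoder(spec),
                              init_decoder(spec, "lung_"),
                              init_decoder(spec, "heart_")))
  structure(list(spec = spec, params = params, seed = seed),
            class = c("semi_siamese_unet", "eit_unet"))
}

#' Build the classical single-decoder U-Net baseline
#'
#' The standard U-Net with one encoder, one decoder and a 2-channel
#' sigmoid head (channel 1 = lung, channel 2 = heart). The encoder
#' topology matches [build_semi_siamese()] exactly, so encoder parameter
#' counts are identical between the two models.
#'
#' @inheritParams build_semi_siamese
#' @return object of class `c("classical_unet", "eit_unet")`.
#' @export
build_baseline <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(seed, c(init_encoder(spec),
                              init_decoder(spec, "dec_", out_channels = 2L)))
  structure(list(spec = spec, params = params, seed = seed),
            class = c("classical_unet", "eit_unet"))
}

model_prefixes <- function(model)
  if (inherits(model, "semi_siamese_unet")) c("lung_", "heart_") else "dec_"

# Forward pass through the full network on a batch.
# x: channels-last matrix (H*W*n, 1). Returns per-head logits and,
# optionally, every intermediate needed for the backward pass.
nn_forward <- function(model, x, n, want_cache = FALSE) {
  spec <- model$spec; par <- model$params
  H <- spec$input_size
  cache <- list(enc = list(), heads = list())
  skips <- list(); sizes <- integer(spec$depth)
  a <- x
  for (l in seq_len(spec$depth)) {
    sizes[l] <- H
    c1 <- conv_fw(a, H, H, n, par[[sprintf("enc%d_c1", l)]], want_cache)
    r1 <- relu_fw(c1$y)
    c2 <- conv_fw(r1, H, H, n, par[[sprintf("enc%d_c2", l)]], want_cache)
    r2 <- relu_fw(c2$y)
    if (want_cache) cache$enc[[l]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2)
    if (l < spec$depth) {
      skips[[l]] <- r2
      p <- pool_fw(r2, H, H, n)
      if (want_cache) cache$enc[[l]]$pool <- p
      a <- p$y
      H <- H %/% 2L
    } else a <- r2
  }
  bottom <- a; Hb <- H
  logits <- list()
  for (pref in model_prefixes(model)) {
    a <- bottom; H <- Hb
    hc <- list()
    for (l in rev(seq_len(spec$depth - 1L))) {
      up <- upsample_fw(a, H, H, n)
      H <- 2L * H
      cu <- conv_fw(up, H, H, n, par[[sprintf("%sd%d_up", pref, l)]], want_cache)
      ru <- relu_fw(cu$y)
      cat_ <- concat_channels(ru, skips[[l]])
      c1 <- conv_fw(cat_, H, H, n, par[[sprintf("%sd%d_c1", pref, l)]], want_cache)
      r1 <- relu_fw(c1$y)
      c2 <- conv_fw(r1, H, H, n, par[[sprintf("%sd%d_c2", pref, l)]], want_cache)
      r2 <- relu_fw(c2$y)
      if (want_cache)
        hc[[l]] <- list(cu = cu, ru = ru, c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                        n_up = ncol(ru))
      a <- r2
    }
    hd <- conv_fw(a, H, H, n, par[[paste0(pref, "head")]], want_cache)
    if (want_cache) { hc$head <- hd; cache$heads[[pref]] <- hc }
    logits[[pref]] <- hd$y
  }
  list(logits = logits,
       cache = if (want_cache)
         c(cache, list(skips = skips, sizes = sizes, bottom_h = Hb, n = n))
       else NULL)
}

# Backward pass: dlogits is a named list matching nn_forward()$logits.
# Returns gradients for every parameter (same names/shapes as params).
nn_backward <- function(model, x, fw, dlogits) {
  spec <- model$spec; par <- model$params; cache <- fw$cache
  n <- cache$n
  grads <- lapply(par, function(p) list(W = p$W * 0, b = p$b * 0))
  d_bottom <- NULL
  d_skips <- vector("list", spec$depth - 1L)
  for (pref in model_prefixes(model)) {
    hc <- cache$heads[[pref]]
    H <- spec$input_size
    bw <- conv_bw(dlogits[[pref]], H, H, n, par[[paste0(pref, "head")]], hc$head)
    nm <- paste0(pref, "head")
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
    da <- bw$dx
    for (l in seq_len(spec$depth - 1L)) {
      lc <- hc[[l]]
      da <- relu_bw(da, lc$r2)
      nm <- sprintf("%sd%d_c2", pref, l)
      bw <- conv_bw(da, H, H, n, par[[nm]], lc$c2)
      grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
      da <- relu_bw(bw$dx, lc$r1)
      nm <- sprintf("%sd%d_c1", pref, l)
      bw <- conv_bw(da, H, H, n, par[[nm]], lc$c1)
      grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
      sp <- split_channels(bw$dx, lc$n_up)
      d_skips[[l]] <- if (is.null(d_skips[[l]])) sp[[2]] else d_skips[[l]] + sp[[2]]
      da <- relu_bw(sp[[1]], lc$ru)
      nm <- sprintf("%sd%d_up", pref, l)
      bw <- conv_bw(da, H, H, n, par[[nm]], lc$cu)
      grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
      H <- H %/% 2L
      da <- upsample_bw(bw$dx, H, H, n)
    }
    d_bottom <- if (is.null(d_bottom)) da else d_bottom + da
  }
  # encoder backward, bottom level first
  da <- d_bottom
  for (l in rev(seq_len(spec$depth))) {
    H <- cache$sizes[l]
    ec <- cache$enc[[l]]
    if (l < spec$depth) {
      da <- pool_bw(da, ec$pool)
      da <- da + d_skips[[l]]
    }
    da <- relu_bw(da, ec$r2)
    nm <- sprintf("enc%d_c2", l)
    bw <- conv_bw(da, H, H, n, par[[nm]], ec$c2)
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
    da <- relu_bw(bw$dx, ec$r1)
    nm <- sprintf("enc%d_c1", l)
    bw <- conv_bw(da, H, H, n, par[[nm]], ec$c1, want_dx = l > 1L)
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW; grads[[nm]]$b <- grads[[nm]]$b + bw$db
    if (l > 1L) da <- bw$dx
  }
  grads
}

# Batched probability forward (no cache): returns per-head (H*W*n, 1)
# matrices of sigmoid probabilities.
nn_predict <- function(model, x, n) {
  lg <- nn_forward(model, x, n, want_cache = FALSE)$logits
  if (inherits(model, "classical_unet")) {
    list(lung_ = sigmoid(lg$dec_[, 1L, drop = FALSE]),
         heart_ = sigmoid(lg$dec_[, 2L, drop = FALSE]))
  } else {
    list(lung_ = sigmoid(lg$lung_), heart_ = sigmoid(lg$heart_))
  }
}

#' Run a model on one EIT image
#'
#' Single-image inference: feeds a normalized 32x32 image through the
#' network and returns the two sigmoid probability maps. All values are
#' strictly inside (0, 1).
#'
#' @param model an `eit_unet` (semi-Siamese or classical).
#' @param image numeric n-by-n matrix, values in \[0, 1\].
#' @return list with `lung` and `heart` probability matrices.
#' @export
forward_pass <- function(model, image) {
  stopifnot(inherits(model, "eit_unet"), is.matrix(image),
            nrow(image) == model$spec$input_size,
            ncol(image) == model$spec$input_size)
  n <- model$spec$input_size
  x <- matrix(as.numeric(image), ncol = 1L)
  pr <- nn_predict(model, x, 1L)
  list(lung = matrix(pr$lung_, n, n), heart = matrix(pr$heart_, n, n))
}

#' Predict probability maps for a batch of images
#'
#' @param object an `eit_unet`.
#' @param images n x n x N array (or a single n x n matrix).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return list with `lung` and `heart` n x n x N probability arrays.
#' @export
predict.eit_unet <- function(object, images, batch_size = 64L, ...) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n <- object$spec$input_size
  stopifnot(dim(images)[1] == n, dim(images)[2] == n)
  N <- dim(images)[3]
  lung <- array(0, c(n, n, N)); heart <- array(0, c(n, n, N))
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    x <- matrix(images[, , idx], ncol = 1L)
    pr <- nn_predict(object, x, length(idx))
    lung[, , idx] <- array(pr$lung_, c(n, n, length(idx)))
    heart[, , idx] <- array(pr$heart_, c(n, n, length(idx)))
  }
  list(lung = lung, heart = heart)
}

#' @export
print.eit_unet <- function(x, ...) {
  kind <- if (inherits(x, "semi_siamese_unet"))
    "Semi-Siamese U-Net (shared encoder, two decoders)"
  else "Classical U-Net baseline (one decoder, two output channels)"
  cat(kind, "\n", sep = "")
  cat("  input ", x$spec$input_size, "x", x$spec$input_size,
      ", depth ", x$spec$depth, ", base channels ", x$spec$base_channels,
      ", parameters ", n_params(x$params), "\n", sep = "")
  invisible(x)
}
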