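# Minimal dense CNN engine used by the U-Net models.
#
# Activations are channels-last matrices of shape (H*W*N, C): rows
# ordered pixel-fastest (column-major over the H x W grid) then batch
# sample, one column per channel. Every convolution is one BLAS matmul
# on an im2col patch matrix assembled in compiled code from contiguous
# shifted copies; pooling and upsampling are row-index gathers whose
# index vectors are cached per activation shape. Input gradients of a
# convolution are computed as a transposed (kernel-flipped) convolution
# through the same im2col kernel. All backward passes are exact
# analytic gradients (verified against finite differences in the test
# suite).

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .idx_cache[[key]]
  if (is.null(v)) { v <- build(); assign(key, v, envir = .idx_cache) }
  v
}

# row index maps for 2x2 pooling on an (H, W) grid with n samples:
# four vectors addressing the (odd/even row, odd/even column) corners of
# every 2x2 block, rows pixel-fastest then sample
pool_indices <- function(H, W, n) {
  key <- paste("p2", H, W, n, sep = "_")
  cache_get(key, function() {
    h2 <- H %/% 2L; w2 <- W %/% 2L
    i2 <- rep(seq_len(h2), times = w2)
    j2 <- rep(seq_len(w2), each = h2)
    base <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                   function(o) (2L * i2 - 1L + o[1]) + (2L * j2 - 2L + o[2]) * H)
    off <- rep((seq_len(n) - 1L) * H * W, each = h2 * w2)
    lapply(base, function(b) rep(b, times = n) + off)
  })
}

# fine-grid row -> coarse-grid source row for 2x nearest upsampling
upsample_indices <- function(H, W, n) {
  key <- paste("u2", H, W, n, sep = "_")
  cache_get(key, function() {
    i <- rep(seq_len(2L * H), times = 2L * W)
    j <- rep(seq_len(2L * W), each = 2L * H)
    src <- ((i + 1L) %/% 2L) + ((j + 1L) %/% 2L - 1L) * H
    off <- rep((seq_len(n) - 1L) * H * W, each = 4L * H * W)
    rep(src, times = n) + off
  })
}

# -- layers -----------------------------------------------------------------

add_bias <- function(y, b) {
  for (cc in seq_along(b)) y[, cc] <- y[, cc] + b[cc]
  y
}

conv_fw <- function(x, H, W, n, par, cache = FALSE) {
  if (par$k == 1L) {
    y <- add_bias(x %*% t(par$W), par$b)
  } else {
    y <- cpp_conv3_fw(x, par$W, par$b, H, W, n)
  }
  if (cache) list(y = y, x = x) else list(y = y)
}

conv_bw <- function(dy, H, W, n, par, cache, want_dx = TRUE) {
  if (par$k == 1L) {
    out <- list(dW = crossprod(dy, cache$x), db = colSums(dy))
    if (want_dx) out$dx <- dy %*% par$W
    out
  } else {
    cpp_conv3_bw(cache$x, dy, par$W, H, W, n, want_dx)
  }
}

relu_fw <- function(x) { x[x < 0] <- 0; x }
relu_bw <- function(dy, y) { dy[y <= 0] <- 0; dy }

pool_fw <- function(x, H, W, n) {
  ix <- pool_indices(H, W, n)
  a1 <- x[ix[[1]], , drop = FALSE]; a2 <- x[ix[[2]], , drop = FALSE]
  a3 <- x[ix[[3]], , drop = FALSE]; a4 <- x[ix[[4]], , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  m1 <- a1 == m
  m2 <- (a2 == m) & !m1
  m3 <- (a3 == m) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(y = m, masks = list(m1, m2, m3, m4), H = H, W = W, n = n)
}

pool_bw <- function(dy, cache) {
  ix <- pool_indices(cache$H, cache$W, cache$n)
  gp <- matrix(0, cache$H * cache$W * cache$n, ncol(dy))
  for (k in 1:4) gp[ix[[k]], ] <- dy * cache$masks[[k]]
  gp
}

upsample_fw <- function(x, H, W, n) x[upsample_indices(H, W, n), , drop = FALSE]

upsample_bw <- function(dy, H, W, n) {
  # H, W are the coarse (input) dims
  ix <- pool_indices(2L * H, 2L * W, n)
  dy[ix[[1]], , drop = FALSE] + dy[ix[[2]], , drop = FALSE] +
    dy[ix[[3]], , drop = FALSE] + dy[ix[[4]], , drop = FALSE]
}

concat_channels <- function(a, b) cbind(a, b)

split_channels <- function(dy, c1)
  list(dy[, seq_len(c1), drop = FALSE], dy[, -seq_len(c1), drop = FALSE])

# -- parameters -------------------------------------------------------------

# He fan-in initialization; ksize 3 or 1.
conv_init <- function(cin, cout, ksize = 3L) {
  fan_in <- ksize * ksize * cin
  list(W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
       b = rep(0, cout), k = as.integer(ksize))
}

n_params <- function(params)
  sum(vapply(params, function(p) length(p$W) + length(p$b), 0))

# -- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g * g
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (state$m[[nm]][[f]] / c1) / (sqrt(state$v[[nm]][[f]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}
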