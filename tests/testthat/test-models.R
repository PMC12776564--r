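test_that("shape contract holds across admissible specs", {
  img <- matrix(runif(32 * 32), 32, 32)
  for (depth in 3:4) for (base in c(8L, 32L)) {
    spec <- model_spec(depth = depth, base_channels = base)
    m <- build_semi_siamese(spec, seed = 1)
    out <- forward_pass(m, img)
    expect_equal(dim(out$lung), c(32, 32))
    expect_equal(dim(out$heart), c(32, 32))
    expect_true(all(out$lung > 0 & out$lung < 1))
    expect_true(all(out$heart > 0 & out$heart < 1))
  }
  expect_error(model_spec(input_size = 30, depth = 4), "input_size")
})

test_that("zeroed terminal heads output exactly 0.5 everywhere", {
  m <- build_semi_siamese(model_spec(depth = 3, base_channels = 8), seed = 5)
  for (nm in c("lung_head", "heart_head")) {
    m$params[[nm]]$W[] <- 0
    m$params[[nm]]$b[] <- 0
  }
  out <- forward_pass(m, matrix(runif(1024), 32, 32))
  expect_equal(out$lung, matrix(0.5, 32, 32))
  expect_equal(out$heart, matrix(0.5, 32, 32))
})

test_that("inference is deterministic for fixed weights and input", {
  m <- build_semi_siamese(model_spec(depth = 3, base_channels = 8), seed = 2)
  img <- matrix(runif(1024), 32, 32)
  expect_identical(forward_pass(m, img), forward_pass(m, img))
  expect_identical(build_semi_siamese(model_spec(), seed = 9)$params,
                   build_semi_siamese(model_spec(), seed = 9)$params)
})

test_that("the encoder is shared and the decoders are independent", {
  spec <- model_spec(depth = 3, base_channels = 8)
  m <- build_semi_siamese(spec, seed = 4)
  img <- matrix(runif(1024), 32, 32)
  base <- forward_pass(m, img)
  # encoder perturbation changes BOTH heads
  m1 <- m; m1$params$enc1_c1$W[1, 1] <- m1$params$enc1_c1$W[1, 1] + 0.5
  out1 <- forward_pass(m1, img)
  expect_false(identical(out1$lung, base$lung))
  expect_false(identical(out1$heart, base$heart))
  # lung-decoder perturbation leaves the heart output bit-identical
  m2 <- m; m2$params$lung_d1_c2$W[1, 1] <- m2$params$lung_d1_c2$W[1, 1] + 0.5
  out2 <- forward_pass(m2, img)
  expect_false(identical(out2$lung, base$lung))
  expect_identical(out2$heart, base$heart)
  # exactly one encoder copy exists
  enc_names <- grep("^enc", names(m$params), value = TRUE)
  expect_length(enc_names, 2 * spec$depth)
})

test_that("baseline has two output channels and fewer parameters, same encoder", {
  spec <- model_spec(depth = 3, base_channels = 8)
  semi <- build_semi_siamese(spec, seed = 1)
  base <- build_baseline(spec, seed = 1)
  expect_equal(nrow(base$params$dec_head$W), 2)
  out <- forward_pass(base, matrix(runif(1024), 32, 32))
  expect_equal(dim(out$lung), c(32, 32))
  expect_true(all(out$heart > 0 & out$heart < 1))
  count <- function(params, pattern)
    sum(vapply(params[grep(pattern, names(params))],
               function(p) length(p$W) + length(p$b), 0))
  expect_equal(count(semi$params, "^enc"), count(base$params, "^enc"))
  expect_equal(count(semi$params, "^lung_"), count(semi$params, "^heart_") )
  expect_lt(count(base$params, ""), count(semi$params, ""))
})

test_that("backpropagation matches finite differences on a small network", {
  set.seed(9)
  spec <- model_spec(input_size = 8, depth = 2, base_channels = 2)
  for (builder in list(build_semi_siamese, build_baseline)) {
    m <- builder(spec, seed = 3)
    # nonzero biases keep pre-activations off the exact ReLU/pooling kinks
    for (nm in names(m$params))
      m$params[[nm]]$b <- rnorm(length(m$params[[nm]]$b), sd = 0.05)
    N <- 2
    x <- matrix(runif(64 * N), ncol = 1)
    tl <- matrix(rbinom(64 * N, 1, 0.3), ncol = 1)
    th <- matrix(rbinom(64 * N, 1, 0.2), ncol = 1)
    w <- loss_weights(1, 1.8)
    lossfun <- function(model) {
      lg <- eitsep:::nn_forward(model, x, N)$logits
      eitsep:::batch_loss_grad(model, lg, tl, th, w, 1e-7)$loss
    }
    fw <- eitsep:::nn_forward(m, x, N, want_cache = TRUE)
    bl <- eitsep:::batch_loss_grad(m, fw$logits, tl, th, w, 1e-7)
    gr <- eitsep:::nn_backward(m, x, fw, bl$dlogits)
    h <- 1e-6
    errs <- c()
    for (nm in names(m$params)) for (f in c("W", "b")) {
      arr <- m$params[[nm]][[f]]
      for (i in sample(length(arr), min(4, length(arr)))) {
        mp <- m; mp$params[[nm]][[f]][i] <- arr[i] + h
        mm <- m; mm$params[[nm]][[f]][i] <- arr[i] - h
        fd <- (lossfun(mp) - lossfun(mm)) / (2 * h)
        errs <- c(errs, abs(fd - gr[[nm]][[f]][i]) /
                    max(abs(fd), abs(gr[[nm]][[f]][i]), 1e-8))
      }
    }
    # a stray pooling tie can distort an isolated finite difference; the
    # bulk of the gradient entries must agree tightly
    expect_lt(median(errs), 1e-6)
    expect_lt(mean(errs > 1e-4), 0.05)
  }
})

test_that("the heart-head loss back-propagates into the shared encoder", {
  spec <- model_spec(input_size = 16, depth = 2, base_channels = 4)
  m <- build_semi_siamese(spec, seed = 6)
  N <- 2
  x <- matrix(runif(256 * N), ncol = 1)
  th <- matrix(rbinom(256 * N, 1, 0.2), ncol = 1)
  fw <- eitsep:::nn_forward(m, x, N, want_cache = TRUE)
  # heart-only loss: zero gradient on the lung logits
  dl <- list(lung_ = fw$logits$lung_ * 0,
             heart_ = (sigmoid(fw$logits$heart_) - th) / length(th))
  gr <- eitsep:::nn_backward(m, x, fw, dl)
  for (l in 1:2) {
    g <- gr[[sprintf("enc%d_c1", l)]]
    expect_gt(sum(abs(g$W)), 0)
  }
  # and no gradient reaches the lung decoder
  expect_equal(sum(abs(gr$lung_d1_c1$W)), 0)
})
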