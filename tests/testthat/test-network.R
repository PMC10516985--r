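tiny_cfg <- function(...) {
  network_config(embed_dim = 8, n_blocks = 2, layers_per_block = 2,
                 window_size = 4, n_heads = 2, ...)
}

test_that("forward pass honours the super-resolution shape contract", {
  m2 <- gft_init(tiny_cfg(sr_scale = 2), seed = 1)
  out <- gft_forward(m2, matrix(runif(16 * 16), 16, 16))
  expect_equal(dim(out), c(32L, 32L))

  m1 <- gft_init(tiny_cfg(sr_scale = 1), seed = 1)
  out <- gft_forward(m1, matrix(runif(16 * 16), 16, 16))
  expect_equal(dim(out), c(16L, 16L))

  # x4 on a 32x64 sensor-shaped input gives 128x256
  m4 <- gft_init(tiny_cfg(sr_scale = 4), seed = 1)
  out <- gft_forward(m4, matrix(runif(32 * 64), 32, 64))
  expect_equal(dim(out), c(128L, 256L))
  expect_true(all(is.finite(out)))
})

test_that("window-incompatible inputs error and enhance() pads them", {
  m <- gft_init(tiny_cfg(sr_scale = 2), seed = 1)
  expect_error(enhance(matrix(0.5, 15, 16), m, pad = FALSE), "window")
  out <- enhance(matrix(0.5, 15, 17), m, pad = TRUE)
  expect_equal(dim(out), c(30L, 34L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("shallow extraction maps to c channels and zero maps to constant", {
  m <- gft_init(tiny_cfg(), seed = 2)
  f0 <- shallow_extract(m, matrix(runif(16 * 16), 16, 16))
  expect_equal(dim(f0), c(1L, 16L, 16L, 8L))
  # zero input: convolution output is the (zero) bias everywhere, so the
  # feature map is spatially constant per channel
  fz <- shallow_extract(m, matrix(0, 16, 16))
  for (ch in 1:8) {
    expect_equal(max(fz[1, , , ch]) - min(fz[1, , , ch]), 0)
  }
})

test_that("dense blocks preserve feature shape and use all inputs", {
  m <- gft_init(tiny_cfg(), seed = 3)
  x <- matrix(runif(16 * 16), 16, 16)
  f0 <- shallow_extract(m, x)
  f1 <- dcstb_forward(m, list(f0), 1)
  expect_equal(dim(f1), dim(f0))
  f2 <- dcstb_forward(m, list(f0, f1), 2)
  expect_equal(dim(f2), dim(f0))
  # second block depends on f1, not just f0
  f2b <- dcstb_forward(m, list(f0, f1 * 2), 2)
  expect_gt(max(abs(f2b - f2)), 0)
})

test_that("gated fusion identities hold to machine precision", {
  set.seed(8)
  feats <- lapply(1:3, function(i) array(rnorm(2 * 4 * 4 * 5), c(2, 4, 4, 5)))
  expect_equal(gated_fusion(feats, c(0, 0, 0)), array(0, c(2, 4, 4, 5)))
  expect_identical(gated_fusion(feats, c(0, 1, 0)), feats[[2]])
  expect_equal(gated_fusion(lapply(feats, function(f) 2 * f), c(0.3, 0.5, 0.2)),
               2 * gated_fusion(feats, c(0.3, 0.5, 0.2)))
  expect_error(gated_fusion(feats, c(1, 2)), "3 feature maps")
})

test_that("every gate weight receives gradient on a random batch", {
  m <- gft_init(tiny_cfg(sr_scale = 2), seed = 4)
  set.seed(9)
  x <- array(runif(2 * 16 * 16), c(2, 16, 16, 1))
  gt <- array(runif(2 * 32 * 32), c(2, 32, 32, 1))
  ag_zero_grad(m$params)
  fwd <- spadkit:::.gft_forward_nodes(m, ag_const(x), training = TRUE)
  l <- spadkit:::.hybrid_loss_nodes(fwd$output, ag_const(gt), loss_config())
  ag_backward(l$total)
  expect_true(all(abs(m$params$gates$grad) > 0))
  # and all other parameters are reached by the tape
  touched <- vapply(m$params, function(p) !is.null(p$grad), logical(1))
  expect_true(all(touched))
})

test_that("first-step gradients are identical across reruns (fixed seed)", {
  grads <- lapply(1:2, function(run) {
    m <- gft_init(tiny_cfg(sr_scale = 2), seed = 5)
    x <- array(matrix(seq(0, 1, length.out = 256), 16, 16), c(1, 16, 16, 1))
    gt <- array(0.5, c(1, 32, 32, 1))
    ag_zero_grad(m$params)
    fwd <- spadkit:::.gft_forward_nodes(m, ag_const(x), training = TRUE)
    l <- spadkit:::.hybrid_loss_nodes(fwd$output, ag_const(gt), loss_config())
    ag_backward(l$total)
    lapply(m$params, function(p) p$grad)
  })
  expect_identical(grads[[1]], grads[[2]])
})

test_that("eval-mode forward is deterministic for fixed weights", {
  m <- gft_init(tiny_cfg(sr_scale = 2), seed = 6)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(gft_forward(m, x), gft_forward(m, x))
})

test_that("network configuration is validated", {
  expect_error(network_config(sr_scale = 3), "sr_scale")
  expect_error(network_config(embed_dim = 10, n_heads = 4), "divisible")
})
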