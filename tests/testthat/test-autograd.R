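# every composite below is checked against central finite differences on
# small random tensors; tolerances are loose relative to machine precision
# but far below any plausible implementation error

grad_check <- function(build, x0, tol = 1e-6) {
  p <- spadkit::ag_param(x0)
  out <- build(p)
  spadkit::ag_zero_grad(list(p))
  spadkit::ag_backward(out)
  num <- numeric_grad(function(x) build(spadkit::ag_const(x))$value, x0)
  expect_lt(max(abs(p$grad - num)) / max(1e-8, max(abs(num))), tol)
}

ag <- function(name) get(name, envir = asNamespace("spadkit"))

test_that("convolution gradients match finite differences", {
  set.seed(42)
  conv <- ag("ag_conv2d"); msq <- function(z) ag("ag_mean")(ag("ag_sq")(z))
  w0 <- array(rnorm(3 * 3 * 2 * 3, sd = 0.3), c(3, 3, 2, 3))
  x0 <- array(rnorm(2 * 6 * 8 * 2), c(2, 6, 8, 2))
  b0 <- rnorm(3)
  grad_check(function(p) msq(conv(p, ag_const(w0), ag_const(b0), "same")), x0)
  grad_check(function(p) msq(conv(ag_const(x0), p, ag_const(b0), "same")), w0)
  grad_check(function(p) msq(conv(ag_const(x0), ag_const(w0), p, "same")), b0)
  grad_check(function(p) msq(conv(p, ag_const(w0), NULL, "valid")), x0)
})

test_that("normalization gradients match finite differences", {
  set.seed(43)
  ln <- ag("ag_layernorm"); bn <- ag("ag_batchnorm")
  msq <- function(z) ag("ag_mean")(ag("ag_sq")(z))
  t0 <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  g0 <- runif(4, 0.5, 1.5); b0 <- rnorm(4)
  grad_check(function(p) msq(ln(p, ag_const(g0), ag_const(b0))), t0)
  grad_check(function(p) msq(ln(ag_const(t0), p, ag_const(b0))), g0)
  x0 <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  bn_f <- function(p) {
    st <- new.env(); st$running_mean <- rep(0, 2); st$running_var <- rep(1, 2)
    msq(bn(p, ag_const(c(1.2, 0.8)), ag_const(c(0.1, -0.2)), st,
           training = TRUE))
  }
  grad_check(bn_f, x0, tol = 1e-4)  # batch-norm variance terms lose precision
})

test_that("attention-shaped gradients match finite differences", {
  set.seed(44)
  msq <- function(z) ag("ag_mean")(ag("ag_sq")(z))
  sm <- ag("ag_softmax_last"); bmm <- ag("ag_bmm"); bt <- ag("ag_btrans")
  s0 <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  grad_check(function(p) msq(sm(p)), s0)
  a0 <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  b0 <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  grad_check(function(p) msq(bmm(sm(bmm(p, bt(ag_const(b0)))), ag_const(b0))),
             a0)
})

test_that("shape-manipulation gradients match finite differences", {
  set.seed(45)
  msq <- function(z) ag("ag_mean")(ag("ag_sq")(z))
  mul <- ag("ag_mul"); roll <- ag("ag_roll"); ps <- ag("ag_pixel_shuffle")
  pool <- ag("ag_avgpool2")
  x0 <- array(rnorm(2 * 3 * 4 * 8), c(2, 3, 4, 8))
  m0 <- array(rnorm(2 * 3 * 4 * 8), c(2, 3, 4, 8))
  grad_check(function(p) msq(mul(roll(p, -1, -2), ag_const(m0))), x0)
  grad_check(function(p) msq(ps(p, 2)), x0)
  grad_check(function(p) msq(pool(p)), array(rnorm(2 * 4 * 4 * 3),
                                             c(2, 4, 4, 3)))
})

test_that("loss-composite gradients match finite differences", {
  set.seed(46)
  x0 <- array(runif(1 * 12 * 12 * 1), c(1, 12, 12, 1))
  y0 <- array(runif(1 * 12 * 12 * 1), c(1, 12, 12, 1))
  cfg <- loss_config(alpha = 0.1, beta = 10, gamma = 100)
  build <- function(p) {
    spadkit:::.hybrid_loss_nodes(p, ag_const(y0), cfg)$total
  }
  grad_check(build, x0, tol = 1e-5)
})

test_that("softmax rows are probability distributions", {
  set.seed(47)
  sm <- ag("ag_softmax_last")
  s <- array(rnorm(6 * 4 * 9), c(6, 4, 9))
  y <- sm(ag_const(s))$value
  expect_equal(rowSums(y, dims = 2), matrix(1, 6, 4), tolerance = 1e-12)
  expect_true(all(y > 0))
})

test_that("gradients accumulate across shared subexpressions", {
  p <- ag_param(2)
  # f = p*p + 3p  ->  df/dp = 2p + 3 = 7
  f <- ag("ag_add")(ag("ag_mul")(p, p), ag("ag_smul")(p, 3))
  ag_backward(f)
  expect_equal(p$grad, 7)
})
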