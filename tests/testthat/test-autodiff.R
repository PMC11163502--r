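# Gradient correctness of the tape: every layer operation is checked
# against central finite differences on small tensors.

grad_check <- function(build_fn, x, n_checks = 6, tol = 1e-5, seed = 123) {
  set.seed(seed)
  node <- nodseg:::ad_input(x)
  out <- build_fn(node)
  w <- array(rnorm(length(out$value)), dim(out$value) %||% length(out$value))
  loss <- nodseg:::new_node(sum(out$value * w), list(out), function(g) list(g * w))
  nodseg:::ad_backward(loss)
  g_analytic <- node$grad
  f <- function(xv) {
    nd <- nodseg:::ad_input(xv)
    sum(build_fn(nd)$value * w)
  }
  idxs <- sample(length(x), n_checks)
  for (i in idxs) {
    gn <- numeric_grad(f, x, i)
    expect_equal(g_analytic[i], gn, tolerance = tol)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution gradients match finite differences", {
  set.seed(201)
  x <- array(rnorm(17 * 16 * 4 * 3 * 2), c(17, 16, 4, 3, 2))
  l <- nodseg:::layer_conv3d(3, 2, c(3, 3, 3))
  grad_check(function(n) nodseg:::op_conv3d(n, l), x)
  # weight gradient (fresh accumulator)
  l$gw <- l$gw * 0
  node <- nodseg:::ad_input(x)
  out <- nodseg:::op_conv3d(node, l)
  set.seed(99); w <- array(rnorm(length(out$value)), dim(out$value))
  loss <- nodseg:::new_node(sum(out$value * w), list(out), function(g) list(g * w))
  nodseg:::ad_backward(loss)
  f <- function(wv) {
    sum(nodseg:::cpp_conv3d_forward(x, wv, l$b, l$stride, l$pad_lo, l$pad_hi) * w)
  }
  for (i in sample(length(l$w), 5)) {
    expect_equal(l$gw[i], numeric_grad(f, l$w, i), tolerance = 1e-5)
  }
})

test_that("strided and asymmetrically padded conv gradients are exact", {
  set.seed(202)
  x <- array(rnorm(16 * 16 * 5 * 2), c(16, 16, 5, 2, 1))
  l <- nodseg:::layer_conv3d(2, 3, c(2, 2, 2), stride = c(2, 2, 1),
                             pad_lo = c(0, 0, 1), pad_hi = c(0, 0, 0))
  grad_check(function(n) nodseg:::op_conv3d(n, l), x)
})

test_that("transposed convolution gradients match finite differences", {
  set.seed(203)
  x <- array(rnorm(8 * 8 * 5 * 4), c(8, 8, 5, 4, 1))
  l <- nodseg:::layer_conv3d_transpose(4, 2, c(2, 2, 2), stride = c(2, 2, 1),
                                       pad_lo = c(0, 0, 1), pad_hi = c(0, 0, 0))
  # geometry: doubles in-plane, keeps z
  node <- nodseg:::ad_input(x)
  out <- nodseg:::op_conv3d_transpose(node, l)
  expect_equal(dim(out$value), c(16, 16, 5, 2, 1))
  grad_check(function(n) nodseg:::op_conv3d_transpose(n, l), x)
})

test_that("batch norm gradients match finite differences in training mode", {
  set.seed(204)
  x <- array(rnorm(6 * 5 * 4 * 3 * 2), c(6, 5, 4, 3, 2))
  build <- function(n) {
    l <- nodseg:::layer_batchnorm(3)
    l$gamma <- c(1.2, 0.8, 1.1); l$beta <- c(0.1, -0.2, 0)
    nodseg:::op_batchnorm(n, l, training = TRUE)
  }
  grad_check(build, x, tol = 1e-4)
})

test_that("PReLU, sigmoid, pooling and SE gradients are exact", {
  set.seed(205)
  x <- array(rnorm(8 * 8 * 3 * 2 * 2), c(8, 8, 3, 2, 2))
  lp <- nodseg:::layer_prelu(2)
  lp$alpha <- c(0.3, 0.15)
  grad_check(function(n) nodseg:::op_prelu(n, lp), x)
  grad_check(function(n) nodseg:::op_sigmoid(n), x)
  grad_check(function(n) nodseg:::op_maxpool(n, k = c(2, 2, 1), s = c(2, 2, 1)), x)
  grad_check(function(n) nodseg:::op_maxpool(n, k = c(3, 3, 3), s = c(1, 1, 1),
                                             same = TRUE), x)
  x16 <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2, 1))
  grad_check(function(n) nodseg:::op_central_pool(n), x16)
  se <- se_block(4, 2)
  x4 <- array(rnorm(6 * 6 * 3 * 4 * 2), c(6, 6, 3, 4, 2))
  grad_check(function(n) nodseg:::se_forward(se, n, FALSE, NULL), x4, tol = 1e-4)
})

test_that("structural ops (concat, tile, upsample, gate) backpropagate", {
  set.seed(206)
  x <- array(rnorm(4 * 4 * 3 * 2 * 2), c(4, 4, 3, 2, 2))
  grad_check(function(n) nodseg:::op_upsample_nearest2(n), x)
  grad_check(function(n) {
    a <- nodseg:::op_affine(n, 2, 1)
    nodseg:::op_concat_channels(n, a)
  }, x)
  x1 <- array(rnorm(4 * 4 * 3 * 1 * 2), c(4, 4, 3, 1, 2))
  grad_check(function(n) nodseg:::op_repeat_channels(n, 5), x1)
  gate_arr <- array(rnorm(4 * 4 * 3 * 1 * 2), c(4, 4, 3, 1, 2))
  grad_check(function(n) nodseg:::op_mul_gate(n, nodseg:::ad_input(gate_arr)), x)
})

test_that("the compound loss node differentiates w.r.t. probabilities", {
  set.seed(207)
  p <- array(runif(5 * 4 * 3, 0.05, 0.95), c(5, 4, 3, 1, 1))
  y <- array(rbinom(60, 1, 0.4), c(5, 4, 3, 1, 1))
  cfg <- loss_config(a = 0.5, wp = 1.3)
  node <- nodseg:::ad_input(p)
  ln <- nodseg:::op_bcedice(node, y, cfg)
  nodseg:::ad_backward(ln)
  f <- function(pv) {
    cfg$a * dice_loss(pv, y) + (1 - cfg$a) * bce_loss(pv, y, cfg)
  }
  for (i in sample(length(p), 6)) {
    expect_equal(node$grad[i], numeric_grad(f, p, i), tolerance = 1e-5)
  }
})

test_that("an end-to-end micro model backpropagates to its input", {
  set.seed(208)
  cfg <- model_config(preset = 6, base_channels = 2, in_plane = 64)
  m <- build_model(cfg)
  x <- array(rnorm(11 * 64 * 64, sd = 0.2), c(1, 1, 11, 64, 64))
  y <- array(rbinom(11 * 64 * 64, 1, 0.05), c(64, 64, 11, 1, 1))
  nodseg:::zero_grads(m)
  fwd <- nodseg:::model_forward(m, x, training = TRUE)
  ln <- nodseg:::op_bcedice(fwd$probs, y, loss_config())
  nodseg:::ad_backward(ln)
  # every trainable layer received a finite, not-all-zero gradient
  gnorms <- vapply(m$layers, function(l) {
    sum(vapply(l$param_names, function(nm)
      sum(abs(get(paste0("g", nm), envir = l))), numeric(1)))
  }, numeric(1))
  expect_true(all(is.finite(gnorms)))
  expect_gt(mean(gnorms > 0), 0.95)
})
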