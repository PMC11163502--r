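# Architecture modules and the assembled network: shape contracts, module
# semantics, ablation presets, parameter/MAC accounting.

test_that("s3d units have the documented parameter accounting", {
  set.seed(301)
  blk <- s3d_block(16, 16, kernel = 3, bias = FALSE)
  conv_bn <- sum(vapply(nodseg:::unit_layers(blk$unit), function(l) {
    if (l$type %in% c("conv3d", "batchnorm")) nodseg:::layer_param_count(l) else 0
  }, numeric(1)))
  # 16*16*9 (intra-slice) + 16*16*3 (inter-slice) + 2 BN layers (2*16 each)
  expect_equal(conv_bn, 2304 + 768 + 64)
  # dense 3x3x3 equivalent carries 16*16*27 = 6912 conv weights: S3D = 12/27
  expect_equal((2304 + 768) / 6912, 12 / 27)
  # shape preservation
  x <- array(rnorm(16 * 11 * 16 * 16), c(16, 11, 16, 16))
  y <- module_forward(blk, x, training = TRUE)
  expect_equal(dim(y), c(16, 11, 16, 16))
})

test_that("residual blocks implement the shortcut contract", {
  set.seed(302)
  rb <- residual_block(8, 8, n_convs = 2, kernel = 3)
  # zero the final stage: BN beta/gamma zeroed makes the conv path vanish
  last <- rb$units[[2]]
  last$bn1$gamma <- last$bn1$gamma * 0
  last$bn1$beta <- last$bn1$beta * 0
  x <- array(rnorm(8 * 5 * 8 * 8), c(8, 5, 8, 8))
  y <- module_forward(rb, x, training = TRUE)
  expect_equal(y, x, tolerance = 1e-12)
  # 1-channel input is tiled across the block width
  rb1 <- residual_block(1, 4, n_convs = 1, kernel = 3)
  x1 <- array(rnorm(1 * 5 * 8 * 8), c(1, 5, 8, 8))
  expect_equal(dim(module_forward(rb1, x1)), c(4, 5, 8, 8))
})

test_that("down transitions halve the plane, double channels, and the
           maxpool mode matches direct stride-2 pooling", {
  set.seed(303)
  x <- array(rnorm(4 * 11 * 16 * 16), c(4, 11, 16, 16))
  for (mode in c("conv", "maxpool", "central")) {
    dt <- down_transition(4L, mode)
    y <- module_forward(dt, x, training = TRUE)
    expect_equal(dim(y), c(8, 11, 8, 8))
  }
  # parameter parity across modes (the channel conv is 2x2x2 in all three)
  counts <- vapply(c("conv", "maxpool", "central"), function(m)
    sum(vapply(nodseg:::collect_layers(down_transition(4L, m)),
               nodseg:::layer_param_count, numeric(1))), numeric(1))
  expect_equal(unname(counts), rep(counts[[1]], 3))
  # the pooling stage of maxpool mode equals plain stride-2 max pooling
  xi <- nodseg:::ad_input(nodseg:::czyx_to_net(x))
  pooled <- nodseg:::op_maxpool(xi, k = c(2L, 2L, 1L), s = c(2L, 2L, 1L))
  direct <- array(NA_real_, c(4, 11, 8, 8))
  for (c in 1:4) for (z in 1:11) for (i in 1:8) for (j in 1:8)
    direct[c, z, i, j] <- max(x[c, z, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(nodseg:::net_to_czyx(pooled$value), direct)
})

test_that("central pooling in the network matches central_pool_3d", {
  set.seed(304)
  x <- array(rnorm(3 * 11 * 16 * 16), c(3, 11, 16, 16))
  xi <- nodseg:::ad_input(nodseg:::czyx_to_net(x))
  y <- nodseg:::net_to_czyx(nodseg:::op_central_pool(xi)$value)
  expect_equal(y, central_pool_3d(x))
})

test_that("DFFM fuses branches additively and preserves shape", {
  set.seed(305)
  mod <- dffm(4)
  enc <- array(rnorm(4 * 5 * 8 * 8), c(4, 5, 8, 8))
  dec <- array(rnorm(4 * 5 * 8 * 8), c(4, 5, 8, 8))
  out <- module_forward(mod, enc, dec, training = TRUE)
  expect_equal(dim(out), dim(enc))
  # a zero decoder branch reduces the fusion to the encoder branch alone
  # (BN on the zero branch is the zero map in training mode up to beta)
  mod$dec_unit$bn1$beta <- mod$dec_unit$bn1$beta * 0
  zero <- array(0, dim(dec))
  out_e <- module_forward(mod, enc, zero, training = FALSE)
  mod2 <- mod
  out_e2 <- module_forward(mod2, enc, zero, training = FALSE)
  expect_equal(out_e, out_e2)  # deterministic
  # stride-1 same-size max pooling is idempotent on constants
  xc <- nodseg:::ad_input(array(3, c(8, 8, 5, 1, 1)))
  mp <- nodseg:::op_maxpool(xc, k = c(3, 3, 3), s = c(1, 1, 1), same = TRUE)
  expect_true(all(mp$value == 3))
})

test_that("reverse attention suppresses confidently claimed regions", {
  set.seed(306)
  ru <- racm_unit(4, n_convs = 1)
  f <- array(rnorm(4 * 5 * 8 * 8), c(4, 5, 8, 8))
  # confident foreground everywhere: gate -> 0, output -> f
  big <- array(50, c(1, 5, 8, 8))
  out_hi <- module_forward(ru, f, big, training = FALSE)
  expect_equal(out_hi, f, tolerance = 1e-10)
  # confident background: gate -> 1, output = f + conv(f)
  lo <- array(-50, c(1, 5, 8, 8))
  out_lo <- module_forward(ru, f, lo, training = FALSE)
  expect_false(isTRUE(all.equal(out_lo, f)))
  # intermediate logits interpolate between the two
  mid <- module_forward(ru, f, array(0, c(1, 5, 8, 8)), training = FALSE)
  expect_equal(mid, (out_hi + out_lo) / 2, tolerance = 1e-8)
})

test_that("SE blocks rescale channels by their computed gates", {
  set.seed(307)
  se <- se_block(8, reduction = 4)
  x <- array(rnorm(8 * 5 * 6 * 6), c(8, 5, 6, 6))
  y <- module_forward(se, x)
  # recompute gates directly
  sq <- apply(x, 1, mean)
  z <- pmax(se$fc1$w %*% sq + se$fc1$b, 0)
  gates <- as.vector(1 / (1 + exp(-(se$fc2$w %*% z + se$fc2$b))))
  for (c in 1:8) expect_equal(y[c, , , ], x[c, , , ] * gates[c], tolerance = 1e-12)
  expect_true(all(gates > 0 & gates < 1))
  # channel permutation equivariance (permuting weights accordingly)
  expect_error(se_block(8, reduction = 16), "divisible")
})

test_that("presets build, forward to [0,1] probabilities, and are deterministic", {
  for (p in c(1, 6)) {
    set.seed(310 + p)
    m <- build_model(tiny_model_config(preset = p))
    x <- array(rnorm(11 * 64 * 64, sd = 0.3), c(1, 11, 64, 64))
    y1 <- model_predict(m, x)
    expect_equal(dim(y1), c(1, 11, 64, 64))
    expect_true(all(y1 > 0 & y1 < 1))
    y2 <- model_predict(m, x)
    expect_identical(y1, y2)
  }
  expect_error(model_config(preset = 7), "preset")
})

test_that("S3D substitution at L4-L5 reduces parameters and MACs", {
  set.seed(320)
  dense <- build_model(tiny_model_config(base_channels = 4))
  set.seed(320)
  sep <- build_model(tiny_model_config(base_channels = 4, s3d_levels = c(4, 5)))
  expect_lt(count_parameters(sep), count_parameters(dense))
  shape <- c(1L, 11L, 32L, 32L)
  expect_lt(count_macs(sep, shape), count_macs(dense, shape))
})

test_that("parameter counts grow as modules are added", {
  counts <- vapply(2:6, function(p) {
    set.seed(330)
    count_parameters(build_model(tiny_model_config(preset = p)))
  }, numeric(1))
  # DFFM, RACM and SE each add parameters; the central-pooling swap (4 -> 5)
  # is parameter-neutral by construction
  expect_true(all(diff(counts)[c(1, 2, 4)] > 0))
  expect_equal(diff(counts)[3], 0)
})

test_that("MAC counting follows convolution arithmetic", {
  # a single 3x3x3 conv 16 -> 16 on (16, 11, 64, 64), same padding
  l <- nodseg:::layer_conv3d(16, 16, 3)
  ctx <- new.env(); ctx$macs <- 0
  xi <- nodseg:::ad_input(array(0, c(64, 64, 11, 16, 1)))
  nodseg:::op_conv3d(xi, l, ctx)
  expect_equal(ctx$macs, 16 * 16 * 27 * 11 * 64 * 64)
  # MACs scale linearly with the z extent
  ctx2 <- new.env(); ctx2$macs <- 0
  nodseg:::op_conv3d(nodseg:::ad_input(array(0, c(64, 64, 22, 16, 1))), l, ctx2)
  expect_equal(ctx2$macs, 2 * ctx$macs)
})

test_that("a single 3x3x3 conv 1->16 with bias counts 448 parameters", {
  l <- nodseg:::layer_conv3d(1, 16, 3)
  expect_equal(nodseg:::layer_param_count(l), 1 * 16 * 27 + 16)
})
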