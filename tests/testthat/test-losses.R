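# Overlap metrics (DSC, OE), the compound Dice+BCE loss, and the fold-level
# t-test.

test_that("DSC and OE satisfy their defining identities", {
  set.seed(7)
  a <- random_mask(c(4, 5, 6))
  expect_equal(dsc(a, a), 1)
  expect_equal(oe(a, a), 0)
  b <- 1 - a  # disjoint from a
  expect_equal(dsc(a, b), 0)
  # TP=2, FP=1, FN=1 worked example
  pred <- c(1, 1, 1, 0, 0)
  gt <- c(1, 1, 0, 1, 0)
  expect_equal(dsc(pred, gt), 4 / 6)
  expect_equal(oe(pred, gt), 0.5)
  # empty-vs-empty conventions
  z <- array(0, c(2, 2))
  expect_equal(dsc(z, z), 1)
  expect_equal(oe(z, z), 0)
  expect_error(dsc(array(0, c(2, 3)), array(0, c(3, 2))), "shape")
  expect_error(dsc(array(0.5, c(2, 2)), z), "binary")
})

test_that("DSC = 2(1-OE)/(2-OE) holds exactly on 1000 random mask pairs", {
  set.seed(8)
  for (i in 1:1000) {
    a <- random_mask(c(4, 4, 4), p = runif(1, 0.05, 0.9))
    b <- random_mask(c(4, 4, 4), p = runif(1, 0.05, 0.9))
    j <- 1 - oe(a, b)
    expect_equal(dsc(a, b), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("Dice loss matches its closed forms", {
  gt <- array(c(rep(1, 8), rep(0, 8)), c(4, 4))
  expect_lt(dice_loss(gt, gt), 1e-5)          # perfect prediction
  # p = 0.5 everywhere on a half-foreground mask -> soft DSC 0.5
  expect_equal(dice_loss(array(0.5, c(4, 4)), gt, eps = 0), 0.5)
  set.seed(9)
  for (i in 1:20) {
    p <- array(runif(64), c(4, 4, 4))
    g <- random_mask(c(4, 4, 4))
    l <- dice_loss(p, g)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  # epsilon -> 0 limit on binary predictions recovers 1 - DSC
  a <- random_mask(c(5, 5)); b <- random_mask(c(5, 5))
  expect_equal(dice_loss(a, b, eps = 1e-8), 1 - dsc(a, b), tolerance = 1e-6)
  expect_error(dice_loss(array(1.5, c(2, 2)), array(1, c(2, 2))), "\\[0, 1\\]")
})

test_that("weighted BCE matches its closed forms and is linear in wp", {
  g <- array(c(rep(1, 8), rep(0, 8)), c(4, 4))   # q = 0.5 foreground
  expect_equal(bce_loss(array(0.5, c(4, 4)), g), log(2), tolerance = 1e-12)
  # wp doubles exactly the foreground term
  l1 <- bce_loss(array(0.5, c(4, 4)), g, loss_config(wp = 1))
  l2 <- bce_loss(array(0.5, c(4, 4)), g, loss_config(wp = 2))
  expect_equal(l2 - l1, log(2) * 0.5, tolerance = 1e-12)
  # confident correct prediction -> about zero
  expect_lt(bce_loss(g, g), 1e-5)
})

test_that("BCEDice is the stated convex combination", {
  set.seed(10)
  p <- array(runif(60), c(3, 4, 5))
  g <- random_mask(c(3, 4, 5))
  expect_identical(bcedice_loss(p, g, loss_config(a = 1)), dice_loss(p, g))
  expect_identical(bcedice_loss(p, g, loss_config(a = 0)),
                   bce_loss(p, g, loss_config(a = 0)))
  ld <- dice_loss(p, g); lb <- bce_loss(p, g)
  l <- bcedice_loss(p, g, loss_config(a = 0.5))
  expect_equal(l, 0.5 * ld + 0.5 * lb)
  expect_gte(l, min(ld, lb)); expect_lte(l, max(ld, lb))
  # worked value: dice 0.5, bce log 2, a = 0.5 -> 0.5966
  gt <- array(c(rep(1, 8), rep(0, 8)), c(4, 4))
  expect_equal(bcedice_loss(array(0.5, c(4, 4)), gt),
               0.5 * dice_loss(array(0.5, c(4, 4)), gt) + 0.5 * log(2),
               tolerance = 1e-12)
  expect_error(loss_config(a = 1.2), "\\[0, 1\\]")
})

test_that("metrics are invariant under simultaneous foreground relabelling", {
  set.seed(11)
  a <- random_mask(c(4, 4)); b <- random_mask(c(4, 4))
  expect_equal(dsc(a, b), dsc(t(a), t(b)))
  expect_equal(oe(a, b), oe(t(a), t(b)))
})

test_that("fold-level t-test matches the pooled closed form", {
  a <- c(84.6, 83.9, 85.1, 84.2, 84.8)
  b <- c(77.8, 78.4, 76.9, 78.1, 77.5)
  res <- t_test_compare(a, b)
  # closed-form pooled-variance t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, length(a) + length(b) - 2)
  expect_lt(res$p, 0.001)
  expect_equal(res$groups$mean, c(mean(a), mean(b)))
  expect_equal(res$groups$sd, c(sd(a), sd(b)))
  # identical groups: t = 0, p = 1
  same <- c(1, 2, 3, 4)
  res0 <- t_test_compare(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # near-complete separation
  res1 <- t_test_compare(c(0, 0, 0, 0) + rnorm(4, sd = 1e-3),
                         c(1, 1, 1, 1) + rnorm(4, sd = 1e-3))
  expect_lt(res1$p, 0.001)
  expect_error(t_test_compare(1, c(1, 2)), "at least 2")
})
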