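# Centre-weighted pooling: kernel-count solver, symmetric layouts, and the
# 1D/2D/3D pooling operators.

test_that("kernel-count solver matches exhaustive enumeration for all valid Q", {
  expect_equal(unname(solve_kernel_counts(64)), c(8, 16, 8))
  expect_equal(unname(solve_kernel_counts(8)), c(1, 2, 1))
  expect_equal(unname(solve_kernel_counts(16)), c(2, 4, 2))
  for (Q in seq(8, 64, by = 8)) {
    sols <- enumerate_kernel_counts(Q)
    expect_equal(nrow(sols), 1L)
    expect_equal(unname(sols[1, ]), unname(solve_kernel_counts(Q)))
  }
  # no solution off the 8-grid: solver errors and enumeration agrees
  for (Q in c(2, 4, 6, 10, 12, 20)) {
    expect_error(solve_kernel_counts(Q), "no non-negative integer solution")
    expect_equal(nrow(enumerate_kernel_counts(Q)), 0L)
  }
  expect_error(solve_kernel_counts(0), "positive")
})

test_that("partition layouts are centrally symmetric and tile the axis", {
  p64 <- build_partition(64)
  expect_equal(p64$layout,
               c(rep(3L, 4), rep(2L, 8), rep(1L, 8), rep(2L, 8), rep(3L, 4)))
  expect_equal(sum(p64$layout), 64)
  expect_equal(length(p64$layout), 32)
  expect_equal(p64$layout, rev(p64$layout))  # palindromic for even counts

  p8 <- build_partition(8)
  expect_equal(p8$layout, c(3L, 2L, 1L, 2L))  # odd size-3 count leads
  expect_equal(sum(p8$layout), 8)
  expect_equal(length(p8$layout), 4)

  for (Q in seq(8, 64, by = 8)) {
    p <- build_partition(Q)
    n <- solve_kernel_counts(Q)
    expect_equal(sum(p$layout), Q)
    expect_equal(length(p$layout), Q / 2)
    expect_equal(as.integer(table(factor(p$layout, levels = 1:3))),
                 unname(n))
    # size-3 windows outermost, size-1 innermost
    expect_true(all(diff(p$layout[1:which.min(p$layout)]) <= 0))
  }
})

test_that("1D central pooling takes window maxima over the stated layout", {
  vals <- c(5, 1, 4, 2, 8, 3, 7, 6)
  expect_equal(central_pool_1d(vals), c(5, 8, 3, 7))
  # constants map to constants
  expect_equal(central_pool_1d(rep(2.5, 16)), rep(2.5, 8))
  # monotone input: each window's max is its last element
  x <- sort(rnorm(24))
  p <- build_partition(24)
  ends <- cumsum(p$layout)
  expect_equal(central_pool_1d(x), x[ends])
  expect_error(central_pool_1d(rnorm(7), build_partition(8)), "length")
})

test_that("2D central pooling equals the direct window-max oracle", {
  set.seed(101)
  for (Q in c(8, 16)) {
    b <- nodseg:::partition_bounds(build_partition(Q))
    for (rep in 1:5) {
      plane <- matrix(rnorm(Q * Q), Q, Q)
      out <- central_pool_2d(plane)
      expect_equal(dim(out), c(Q / 2, Q / 2))
      for (i in seq_along(b$starts)) for (j in seq_along(b$starts)) {
        expect_equal(out[i, j],
                     max(plane[b$starts[i] + seq_len(b$lens[i]),
                               b$starts[j] + seq_len(b$lens[j])]))
      }
    }
  }
  # a hot pixel at the exact centre lands in a size-1 centre window
  # (Q = 16: the two size-1 windows straddle the midpoint, 0-based 7 and 8)
  plane <- matrix(0, 16, 16)
  plane[8, 8] <- 9
  out <- central_pool_2d(plane)
  expect_equal(out[4, 4], 9)
  expect_equal(sum(out == 9), 1)
  # Q = 8 (odd counts): the single size-1 window sits at 0-based index 5
  plane8 <- matrix(0, 8, 8)
  plane8[6, 6] <- 9
  out8 <- central_pool_2d(plane8)
  expect_equal(out8[3, 3], 9)
  expect_equal(sum(out8 == 9), 1)
  expect_error(central_pool_2d(matrix(0, 8, 6)), "square")
})

test_that("3D central pooling follows the slice-axis rule", {
  set.seed(102)
  blk <- array(rnorm(2 * 11 * 16 * 16), c(2, 11, 16, 16))
  out <- central_pool_3d(blk)
  expect_equal(dim(out), c(2, 11, 8, 8))        # z = 11 left unpooled
  blk8 <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  expect_equal(dim(central_pool_3d(blk8)), c(1, 4, 8, 8))
  expect_equal(dim(central_pool_3d(blk8, pool_z = FALSE)), c(1, 8, 8, 8))
  # per-channel independence: permuting channels commutes with pooling
  perm <- c(2, 1)
  expect_equal(central_pool_3d(blk[perm, , , ]), central_pool_3d(blk)[perm, , , ])
  # constants
  expect_equal(central_pool_3d(array(1, c(1, 3, 8, 8))),
               array(1, c(1, 3, 4, 4)))
})

test_that("pooling is monotone and bounded by the input max", {
  set.seed(103)
  for (rep in 1:20) {
    a <- array(rnorm(1 * 5 * 16 * 16), c(1, 5, 16, 16))
    b <- a - abs(array(rnorm(length(a)), dim(a)))  # b <= a elementwise
    pa <- central_pool_3d(a)
    pb <- central_pool_3d(b)
    expect_true(all(pa >= pb))
    expect_lte(max(pa), max(a))
    expect_gte(min(pa), min(a))
  }
})
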