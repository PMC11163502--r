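#' Kernel counts for centre-weighted pooling
#'
#' Central pooling tiles an axis of even length `Q` with `n1` windows of
#' size 1, `n2` of size 2 and `n3` of size 3, subject to
#' \deqn{n_1 + 2 n_2 + 3 n_3 = Q, \quad n_1 + n_2 + n_3 = Q/2, \quad
#'       n_1 + n_3 = n_2,}
#' i.e. the windows cover the axis, the output is half the input length
#' (the same ratio as stride-2 max pooling), and the size-2 windows make up
#' half of all windows. The unique non-negative integer solution is
#' `(Q/8, Q/4, Q/8)`, which exists iff `Q` is divisible by 8.
#'
#' @param Q positive integer axis length, divisible by 8.
#' @return integer vector `c(n1, n2, n3)`.
#' @export
solve_kernel_counts <- function(Q) {
  Q <- as.integer(Q)
  if (length(Q) != 1L || is.na(Q) || Q <= 0)
    stop("solve_kernel_counts: Q must be a positive integer")
  if (Q %% 8L != 0L)
    stop("solve_kernel_counts: no non-negative integer solution for Q = ", Q,
         "; the system requires Q divisible by 8 (closed form n = (Q/8, Q/4, Q/8))")
  c(n1 = Q %/% 8L, n2 = Q %/% 4L, n3 = Q %/% 8L)
}

#' Exhaustive solver for the pooling-count system (reference oracle)
#'
#' Enumerates all triples `0..Q` and returns those satisfying the three
#' constraints of [solve_kernel_counts()]. Intended for validation.
#'
#' @param Q positive integer.
#' @return matrix with columns n1, n2, n3 (0 or 1 rows).
#' @export
enumerate_kernel_counts <- function(Q) {
  Q <- as.integer(Q)
  sols <- NULL
  for (n3 in 0:(Q %/% 3L)) for (n2 in 0:(Q %/% 2L)) {
    n1 <- Q - 2L * n2 - 3L * n3
    if (n1 < 0L) next
    if (n1 + n2 + n3 == Q / 2 && n1 + n3 == n2)
      sols <- rbind(sols, c(n1 = n1, n2 = n2, n3 = n3))
  }
  if (is.null(sols)) matrix(integer(0), ncol = 3,
                            dimnames = list(NULL, c("n1", "n2", "n3")))
  else sols
}

#' Centrally symmetric pooling layout for one axis
#'
#' Orders the windows so that the large (size-3) windows sit at the axis
#' ends, size-2 windows next, and the size-1 windows at the centre, where
#' the (nodule-centred) target lies:
#' `[3 x n3/2, 2 x n2/2, 1 x n1, 2 x n2/2, 3 x n3/2]`. When `n2` or `n3`
#' is odd the extra window goes on the leading (low-index) side.
#'
#' @param Q axis length, divisible by 8.
#' @return An object of class `pooling_partition` with fields
#'   `axis_length`, `counts` and `layout` (window sizes, left to right).
#' @export
build_partition <- function(Q) {
  n <- solve_kernel_counts(Q)
  lead3 <- ceiling(n[["n3"]] / 2)
  lead2 <- ceiling(n[["n2"]] / 2)
  layout <- c(rep(3L, lead3), rep(2L, lead2), rep(1L, n[["n1"]]),
              rep(2L, n[["n2"]] - lead2), rep(3L, n[["n3"]] - lead3))
  structure(list(axis_length = as.integer(Q), counts = n,
                 layout = as.integer(layout)),
            class = "pooling_partition")
}

#' @export
print.pooling_partition <- function(x, ...) {
  cat(sprintf("<pooling_partition> Q = %d, counts (n1,n2,n3) = (%d,%d,%d)\n",
              x$axis_length, x$counts[1], x$counts[2], x$counts[3]))
  cat("  layout:", paste(x$layout, collapse = " "), "\n")
  invisible(x)
}

partition_bounds <- function(partition) {
  lens <- partition$layout
  starts <- cumsum(c(0L, lens[-length(lens)]))
  list(starts = as.integer(starts), lens = as.integer(lens))
}

#' 1D central pooling
#'
#' Max-pools a length-`Q` vector over the contiguous windows of a
#' [build_partition()] layout, producing `Q/2` values.
#'
#' @param values numeric vector of length `partition$axis_length`.
#' @param partition a `pooling_partition`; defaults to
#'   `build_partition(length(values))`.
#' @return numeric vector of length `Q/2`.
#' @export
central_pool_1d <- function(values, partition = build_partition(length(values))) {
  if (length(values) != partition$axis_length)
    stop("central_pool_1d: length(values) = ", length(values),
         " but partition covers ", partition$axis_length)
  b <- partition_bounds(partition)
  vapply(seq_along(b$starts),
         function(i) max(values[(b$starts[i] + 1L):(b$starts[i] + b$lens[i])]),
         numeric(1))
}

#' 2D central pooling
#'
#' Separable application of [central_pool_1d()] along both axes of a square
#' `Q x Q` plane: each output cell is the max over the rectangular window
#' formed by the Cartesian product of the two axis layouts.
#'
#' @param plane numeric `Q x Q` matrix, `Q` divisible by 8.
#' @return `(Q/2) x (Q/2)` matrix.
#' @export
central_pool_2d <- function(plane) {
  d <- dim(plane)
  if (is.null(d) || length(d) != 2L || d[1] != d[2])
    stop("central_pool_2d: input must be a square matrix")
  part <- build_partition(d[1])
  b <- partition_bounds(part)
  nw <- length(b$starts)
  out <- matrix(NA_real_, nw, nw)
  for (i in seq_len(nw)) for (j in seq_len(nw)) {
    out[i, j] <- max(plane[(b$starts[i] + 1L):(b$starts[i] + b$lens[i]),
                           (b$starts[j] + 1L):(b$starts[j] + b$lens[j])])
  }
  out
}

#' 3D central pooling
#'
#' Applies 2D central pooling to every `(y, x)` plane of a `C x Z x Q x Q`
#' feature block. The slice axis is pooled with the 1D layout only when `Z`
#' is itself divisible by 8; otherwise (e.g. the 11-slice stacks used here)
#' `z` is left unpooled so the inter-slice structure of the 2.5D input is
#' preserved.
#'
#' @param block numeric array `(C, Z, Q, Q)`.
#' @param pool_z attempt to pool the slice axis when divisible by 8.
#' @return array `(C, Z', Q/2, Q/2)` with `Z' = Z/2` or `Z`.
#' @export
central_pool_3d <- function(block, pool_z = TRUE) {
  d <- dim(block)
  if (length(d) != 4L || d[3] != d[4])
    stop("central_pool_3d: expected (C, Z, Q, Q) with square planes")
  Q <- d[3]
  bp <- partition_bounds(build_partition(Q))
  if (pool_z && d[2] %% 8L == 0L) {
    bz <- partition_bounds(build_partition(d[2]))
  } else {
    bz <- list(starts = 0:(d[2] - 1L), lens = rep(1L, d[2]))
  }
  x <- aperm(block, c(4, 3, 2, 1))           # (x, y, z, c)
  dim(x) <- c(d[4], d[3], d[2], d[1], 1L)    # add batch dim
  res <- cpp_pool_windows(x, bp$starts, bp$lens, bp$starts, bp$lens,
                          bz$starts, bz$lens)
  v <- res$value
  dv <- dim(v)
  dim(v) <- dv[1:4]
  aperm(v, c(4, 3, 2, 1))
}
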