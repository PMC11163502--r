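# Reverse-mode automatic differentiation on a dynamically built tape.
#
# Feature tensors are plain numeric arrays with dim = (X, Y, Z, C, N)
# (x fastest, matching the compiled kernels). A tape node is an environment
# holding the forward value, a list of parent nodes, and a backward closure
# that maps the node's output gradient to a list of parent gradients
# (accumulating any parameter gradients into the owning layer as a side
# effect). `ad_backward()` runs a topological sweep from a scalar loss node.

.nodseg_state <- new.env(parent = emptyenv())
.nodseg_state$node_counter <- 0L

new_node <- function(value, parents = list(), backfn = NULL) {
  .nodseg_state$node_counter <- .nodseg_state$node_counter + 1L
  e <- new.env(parent = emptyenv())
  e$id <- .nodseg_state$node_counter
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

ad_input <- function(value) new_node(value)

ad_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Topologically ordered backward sweep from a scalar node.
ad_backward <- function(loss_node) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss_node, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  loss_node$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    pgrads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(pgrads[[j]])) ad_accumulate(node$parents[[j]], pgrads[[j]])
    }
    node$grad <- NULL  # free memory as we go
    node$value <- NULL
    node$backfn <- NULL  # drop closure references to cached activations
  }
  invisible(NULL)
}

# ---- elementwise / structural ops -----------------------------------------

op_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  new_node(a$value * b$value, list(a, b),
           function(g) list(g * b$value, g * a$value))
}

op_affine <- function(a, scale, shift) {
  new_node(scale * a$value + shift, list(a), function(g) list(scale * g))
}

op_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

# Per-channel broadcast helper: expand a length-C vector over (X,Y,Z,C,N).
chan_expand <- function(v, d) rep(rep(v, times = d[5]), each = prod(d[1:3]))

chan_reduce <- function(arr, d) {
  S <- prod(d[1:3])
  rowSums(matrix(.colSums(matrix(arr, nrow = S), S, d[4] * d[5]), d[4], d[5]))
}

op_prelu <- function(a, layer) {
  d <- dim(a$value)
  y <- {  # temporaries die with this block; backward recomputes from a$value
    x <- a$value
    af <- chan_expand(layer$alpha, d)
    out <- pmax(x, 0) + af * pmin(x, 0)
    dim(out) <- d
    out
  }
  new_node(y, list(a), function(g) {
    x <- a$value
    neg <- (x < 0)
    layer$galpha <- layer$galpha + chan_reduce(g * (x * neg), d)
    af <- chan_expand(layer$alpha, d)
    gx <- g * (!neg) + (g * af) * neg
    dim(gx) <- d
    list(gx)
  })
}

op_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(identical(da[c(1:3, 5)], db[c(1:3, 5)]))
  v <- array(0, dim = c(da[1:3], da[4] + db[4], da[5]))
  v[, , , seq_len(da[4]), ] <- a$value
  v[, , , da[4] + seq_len(db[4]), ] <- b$value
  new_node(v, list(a, b), function(g) {
    list(g[, , , seq_len(da[4]), , drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), , drop = FALSE])
  })
}

op_repeat_channels <- function(a, times) {
  d <- dim(a$value)
  stopifnot(d[4] == 1L)
  v <- a$value[, , , rep(1L, times), , drop = FALSE]
  new_node(v, list(a), function(g) {
    gs <- g[, , , 1L, , drop = FALSE]
    if (times > 1L) for (c in 2:times) gs <- gs + g[, , , c, , drop = FALSE]
    list(gs)
  })
}

op_upsample_nearest2 <- function(a) {
  d <- dim(a$value)
  v <- a$value[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , ,
               drop = FALSE]
  new_node(v, list(a), function(g) {
    o1 <- seq(1L, 2L * d[1], by = 2L)
    p1 <- seq(1L, 2L * d[2], by = 2L)
    gx <- g[o1, p1, , , , drop = FALSE] + g[o1 + 1L, p1, , , , drop = FALSE] +
      g[o1, p1 + 1L, , , , drop = FALSE] + g[o1 + 1L, p1 + 1L, , , , drop = FALSE]
    list(gx)
  })
}

# ---- convolution ----------------------------------------------------------

op_conv3d <- function(a, layer, ctx = NULL) {
  y <- cpp_conv3d_forward(a$value, layer$w,
                          if (layer$use_bias) layer$b else NULL,
                          layer$stride, layer$pad_lo, layer$pad_hi)
  if (!is.null(ctx)) {
    dy <- dim(y)
    ctx$macs <- ctx$macs + prod(dim(layer$w)) * prod(dy[1:3]) * dy[5]
  }
  new_node(y, list(a), function(g) {
    res <- cpp_conv3d_backward(a$value, layer$w, g, layer$stride, layer$pad_lo,
                               layer$pad_hi, TRUE, TRUE)
    layer$gw <- layer$gw + res$gw
    if (layer$use_bias) {
      d <- dim(g)
      S <- prod(d[1:3])
      layer$gb <- layer$gb +
        rowSums(matrix(.colSums(matrix(g, nrow = S), S, d[4] * d[5]), d[4], d[5]))
    }
    list(res$gx)
  })
}

op_conv3d_transpose <- function(a, layer, ctx = NULL) {
  d <- dim(a$value)
  # output extent of the transposed map = input extent of the virtual conv
  out_sp <- (d[1:3] - 1L) * layer$stride + dim(layer$w)[1:3] -
    layer$pad_lo - layer$pad_hi
  xdim <- as.integer(c(out_sp, dim(layer$w)[4], d[5]))
  y <- cpp_conv3d_grad_data(a$value, layer$w, xdim, layer$stride, layer$pad_lo,
                            layer$pad_hi)
  if (layer$use_bias) {
    S <- prod(out_sp)
    y <- y + rep(rep(layer$b, times = d[5]), each = S)
    dim(y) <- xdim
  }
  if (!is.null(ctx))
    ctx$macs <- ctx$macs + prod(dim(layer$w)) * prod(d[1:3]) * d[5]
  new_node(y, list(a), function(g) {
    gin <- cpp_conv3d_forward(g, layer$w, NULL, layer$stride, layer$pad_lo,
                              layer$pad_hi)
    res <- cpp_conv3d_backward(g, layer$w, a$value, layer$stride, layer$pad_lo,
                               layer$pad_hi, FALSE, TRUE)
    layer$gw <- layer$gw + res$gw
    if (layer$use_bias) {
      S <- prod(out_sp)
      layer$gb <- layer$gb +
        rowSums(matrix(.colSums(matrix(g, nrow = S), S, dim(g)[4] * dim(g)[5]),
                       dim(g)[4], dim(g)[5]))
    }
    list(gin)
  })
}

# ---- batch normalisation ---------------------------------------------------

# mode: TRUE/"train" = batch stats + update running averages;
# "batch" = batch stats without updating (single-sample inference);
# FALSE/"running" = stored running averages.
op_batchnorm <- function(a, layer, training) {
  mode <- if (isTRUE(training)) "train" else if (identical(training, "batch"))
    "batch" else "running"
  d <- dim(a$value)
  S <- prod(d[1:3])
  C <- d[4]; N <- d[5]
  if (mode != "running") {
    xm <- matrix(a$value, nrow = S)
    cm <- .colMeans(xm, S, C * N)
    mu <- rowMeans(matrix(cm, C, N))
    cm2 <- .colMeans(xm * xm, S, C * N)
    v <- pmax(rowMeans(matrix(cm2, C, N)) - mu^2, 0)
    if (mode == "train") {
      layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
        layer$momentum * mu
      layer$running_var <- (1 - layer$momentum) * layer$running_var +
        layer$momentum * v
    }
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  # only per-channel vectors are kept; full-size temporaries are rebuilt
  # from the parent value during backward
  y <- {
    scale <- layer$gamma * invstd
    out <- a$value * chan_expand(scale, d) +
      chan_expand(layer$beta - mu * scale, d)
    dim(out) <- d
    out
  }
  new_node(y, list(a), function(g) {
    is_full <- chan_expand(invstd, d)
    xhat <- (a$value - chan_expand(mu, d)) * is_full
    ggamma <- chan_reduce(g * xhat, d)
    gbeta <- chan_reduce(g, d)
    layer$ggamma <- layer$ggamma + ggamma
    layer$gbeta <- layer$gbeta + gbeta
    gs_full <- chan_expand(layer$gamma, d) * is_full
    if (mode != "running") {
      m <- S * N
      gx <- gs_full * g -
        (gs_full / m) * (chan_expand(gbeta, d) + xhat * chan_expand(ggamma, d))
    } else {
      gx <- g * gs_full
    }
    dim(gx) <- d
    list(gx)
  })
}

# ---- pooling ---------------------------------------------------------------

# Uniform max pooling expressed as explicit window bounds (same-padding is
# realised by clamping windows at the borders, i.e. padding never wins).
uniform_bounds <- function(n, k, s, same = FALSE) {
  if (same) {
    centers <- seq.int(0L, n - 1L)
    lo <- pmax(centers - (k %/% 2L), 0L)
    hi <- pmin(centers + ((k - 1L) %/% 2L), n - 1L)
    list(starts = as.integer(lo), lens = as.integer(hi - lo + 1L))
  } else {
    n_out <- (n - k) %/% s + 1L
    list(starts = as.integer(seq.int(0L, by = s, length.out = n_out)),
         lens = rep(as.integer(k), n_out))
  }
}

op_pool_bounds <- function(a, bx, by, bz) {
  din <- dim(a$value)
  res <- cpp_pool_windows(a$value, bx$starts, bx$lens, by$starts, by$lens,
                          bz$starts, bz$lens)
  amax <- res$argmax
  new_node(res$value, list(a), function(g) {
    gx <- cpp_pool_backward(g, amax, prod(din))
    dim(gx) <- din
    list(gx)
  })
}

op_maxpool <- function(a, k, s, same = FALSE) {
  d <- dim(a$value)
  op_pool_bounds(a,
                 uniform_bounds(d[1], k[1], s[1], same),
                 uniform_bounds(d[2], k[2], s[2], same),
                 uniform_bounds(d[3], k[3], s[3], same))
}

# Central pooling over the in-plane axes (x, y); the slice axis is pooled
# only when divisible by 8, mirroring central_pool_3d().
op_central_pool <- function(a, pool_z = FALSE) {
  d <- dim(a$value)
  stopifnot(d[1] == d[2])
  b <- partition_bounds(build_partition(d[1]))
  bz <- if (pool_z && d[3] %% 8L == 0L) partition_bounds(build_partition(d[3]))
        else list(starts = seq.int(0L, d[3] - 1L), lens = rep(1L, d[3]))
  op_pool_bounds(a, b, b, bz)
}

# ---- squeeze-and-excite helpers -------------------------------------------

op_global_avg_pool <- function(a) {
  d <- dim(a$value)
  S <- prod(d[1:3])
  v <- matrix(.colMeans(matrix(a$value, nrow = S), S, d[4] * d[5]), d[4], d[5])
  new_node(v, list(a), function(g) {
    gx <- rep(as.vector(g), each = S) / S
    dim(gx) <- d
    list(gx)
  })
}

op_dense <- function(a, layer) {
  x <- a$value  # (C_in, N)
  y <- layer$w %*% x + layer$b
  new_node(y, list(a), function(g) {
    layer$gw <- layer$gw + g %*% t(x)
    layer$gb <- layer$gb + rowSums(g)
    list(t(layer$w) %*% g)
  })
}

op_sigmoid_mat <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

op_relu_mat <- function(a) {
  y <- pmax(a$value, 0)
  new_node(y, list(a), function(g) list(g * (a$value > 0)))
}

# Scale each channel of `a` by the (C, N) gate matrix `s`.
op_scale_channels <- function(a, s) {
  d <- dim(a$value)
  S <- prod(d[1:3])
  y <- a$value * rep(as.vector(s$value), each = S)
  dim(y) <- d
  new_node(y, list(a, s), function(g) {
    gx <- g * rep(as.vector(s$value), each = S)
    dim(gx) <- d
    gs <- matrix(.colSums(matrix(g * a$value, nrow = S), S, d[4] * d[5]),
                 d[4], d[5])
    list(gx, gs)
  })
}

# ---- loss ------------------------------------------------------------------

# Compound Dice + weighted BCE on sigmoid probabilities; returns a scalar
# node differentiable w.r.t. the probability tensor.
op_bcedice <- function(probs, target, cfg, eps = 1e-5, delta = 1e-7) {
  p <- probs$value
  y <- as.numeric(target)
  n <- length(p)
  inter <- sum(p * y)
  psum <- sum(p)
  gsum <- sum(y)
  ldice <- 1 - (2 * inter + eps) / (psum + gsum + eps)
  pc <- pmin(pmax(p, delta), 1 - delta)
  lbce <- -mean(cfg$wp * y * log(pc) + (1 - y) * log(1 - pc))
  val <- cfg$a * ldice + (1 - cfg$a) * lbce
  new_node(val, list(probs), function(g) {
    denom <- psum + gsum + eps
    gdice <- -(2 * y * denom - (2 * inter + eps)) / denom^2
    inside <- (p >= delta) & (p <= 1 - delta)
    gbce <- (-(cfg$wp * y / pc) + (1 - y) / (1 - pc)) / n
    gbce[!inside] <- 0
    gp <- g * (cfg$a * gdice + (1 - cfg$a) * gbce)
    dim(gp) <- dim(p)
    list(gp)
  })
}
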