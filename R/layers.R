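# Trainable layer containers. Each layer is an environment holding its
# parameter arrays, matching gradient accumulators (g<name>) and, once an
# optimiser touches it, Adam moment buffers. Geometry vectors are in
# (x, y, z) order to match the compiled kernels.

new_layer <- function(type, param_names, fields) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- param_names
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  for (nm in param_names) assign(paste0("g", nm), fields[[nm]] * 0, envir = e)
  class(e) <- "nn_layer"
  e
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

layer_conv3d <- function(in_ch, out_ch, kernel, stride = c(1L, 1L, 1L),
                         pad_lo = NULL, pad_hi = NULL, bias = TRUE) {
  kernel <- as.integer(rep(kernel, length.out = 3))
  if (is.null(pad_lo)) {  # same padding (asymmetric for even kernels)
    pad_lo <- kernel %/% 2L
    pad_hi <- (kernel - 1L) %/% 2L
  }
  w <- he_init(c(kernel, in_ch, out_ch), prod(kernel) * in_ch)
  fields <- list(w = w, stride = as.integer(stride),
                 pad_lo = as.integer(pad_lo), pad_hi = as.integer(pad_hi),
                 use_bias = bias)
  pn <- "w"
  if (bias) {
    fields$b <- numeric(out_ch)
    pn <- c("w", "b")
  }
  new_layer("conv3d", pn, fields)
}

layer_conv3d_transpose <- function(in_ch, out_ch, kernel, stride,
                                   pad_lo = c(0L, 0L, 0L),
                                   pad_hi = c(0L, 0L, 0L), bias = TRUE) {
  kernel <- as.integer(rep(kernel, length.out = 3))
  # weight follows the virtual (adjoint) convolution: out_ch -> in_ch
  w <- he_init(c(kernel, out_ch, in_ch), prod(kernel) * in_ch)
  fields <- list(w = w, stride = as.integer(stride),
                 pad_lo = as.integer(pad_lo), pad_hi = as.integer(pad_hi),
                 use_bias = bias)
  pn <- "w"
  if (bias) {
    fields$b <- numeric(out_ch)
    pn <- c("w", "b")
  }
  new_layer("conv3d_transpose", pn, fields)
}

layer_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("batchnorm", c("gamma", "beta"), list(
    gamma = rep(1, channels), beta = numeric(channels),
    running_mean = numeric(channels), running_var = rep(1, channels),
    momentum = momentum, eps = eps
  ))
}

layer_prelu <- function(channels, init = 0.25) {
  new_layer("prelu", "alpha", list(alpha = rep(init, channels)))
}

layer_dense <- function(in_ch, out_ch) {
  new_layer("dense", c("w", "b"), list(
    w = matrix(rnorm(out_ch * in_ch, sd = sqrt(2 / in_ch)), out_ch, in_ch),
    b = numeric(out_ch)
  ))
}

layer_param_count <- function(layer) {
  sum(vapply(layer$param_names, function(nm) length(get(nm, envir = layer)),
             numeric(1)))
}

# A conv "unit" = convolution(s) + batch norm + PReLU. With `s3d = TRUE`
# the k x k x k kernel is factorised into an intra-slice (1, k, k)
# convolution and an inter-slice (k, 1, 1) convolution, each followed by
# batch normalisation and its own activation.
make_conv_unit <- function(in_ch, out_ch, kernel, s3d = FALSE, bias = TRUE) {
  kernel <- as.integer(rep(kernel, length.out = 3))
  u <- list(s3d = s3d)
  if (s3d) {
    u$conv1 <- layer_conv3d(in_ch, out_ch, c(kernel[1], kernel[2], 1L), bias = bias)
    u$bn1 <- layer_batchnorm(out_ch)
    u$act1 <- layer_prelu(out_ch)
    u$conv2 <- layer_conv3d(out_ch, out_ch, c(1L, 1L, kernel[3]), bias = bias)
    u$bn2 <- layer_batchnorm(out_ch)
    u$act2 <- layer_prelu(out_ch)
  } else {
    u$conv1 <- layer_conv3d(in_ch, out_ch, kernel, bias = bias)
    u$bn1 <- layer_batchnorm(out_ch)
    u$act1 <- layer_prelu(out_ch)
  }
  u
}

unit_forward <- function(u, x, training, ctx) {
  h <- op_conv3d(x, u$conv1, ctx)
  h <- op_batchnorm(h, u$bn1, training)
  h <- op_prelu(h, u$act1)
  if (isTRUE(u$s3d)) {
    h <- op_conv3d(h, u$conv2, ctx)
    h <- op_batchnorm(h, u$bn2, training)
    h <- op_prelu(h, u$act2)
  }
  h
}

unit_layers <- function(u) {
  Filter(function(z) inherits(z, "nn_layer"), u)
}
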