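#' Model configuration and ablation presets
#'
#' Describes the 2.5D V-Net variant: a 5-level residual encoder--decoder
#' (channel widths doubling from `base_channels`) with optional separable-3D
#' (S3D) convolution stages, dual-branch feature fusion (DFFM) on the skip
#' connections, two serial reverse-attention context modules (RACM) in the
#' decoder, centre-weighted pooling in the down-transitions, and
#' squeeze-and-excite (SE) channel gating after each decoder stage.
#'
#' The six ablation presets are:
#' \describe{
#'   \item{1}{plain V-Net baseline (5x5x5 convolutions, strided-convolution
#'     down-transitions, no add-on modules)}
#'   \item{2}{S3D V-Net: the bottleneck convolutions factorised into
#'     intra-slice + inter-slice pairs}
#'   \item{3}{preset 2 + DFFM}
#'   \item{4}{preset 3 + RACM}
#'   \item{5}{preset 4 + central pooling down-transitions}
#'   \item{6}{preset 5 + SE (the full model)}
#' }
#'
#' The slice axis is never down-sampled (the 11-slice stack is odd), so all
#' transitions act in-plane; inter-slice context enters through the
#' 3D/S3D kernels.
#'
#' @param preset integer 1--6 selecting an ablation row, or `NULL` for a
#'   fully manual configuration.
#' @param base_channels width of the first level (doubles per level).
#' @param enc_convs,dec_convs convolutions per encoder level (5 values) and
#'   per decoder stage (4 values, deepest first).
#' @param kernel isotropic convolution kernel extent (default 5, the V-Net
#'   convention).
#' @param s3d_levels encoder levels whose convolutions are factorised into
#'   S3D pairs.
#' @param down_mode `"conv"` (strided 2x2x2 convolution), `"maxpool"`
#'   (uniform stride-2 max pooling + channel-doubling convolution) or
#'   `"central"` (central pooling + channel-doubling convolution).
#' @param use_dffm,use_racm,use_se module switches.
#' @param se_reduction SE bottleneck reduction ratio; must divide every
#'   decoder stage width.
#' @param racm_stages decoder stages (levels, deepest = 4) hosting the two
#'   serial RACM units.
#' @param racm_convs convolutions inside each RACM unit.
#' @param dffm_kernel kernel extent of the DFFM branch convolutions.
#' @param in_slices,in_plane expected input geometry (11 and 64).
#' @return An object of class `model_config`.
#' @export
model_config <- function(preset = NULL, base_channels = 16L,
                         enc_convs = c(1L, 1L, 2L, 3L, 2L),
                         dec_convs = c(2L, 2L, 1L, 1L),
                         kernel = 5L, s3d_levels = integer(0),
                         down_mode = c("conv", "maxpool", "central"),
                         use_dffm = FALSE, use_racm = FALSE, use_se = FALSE,
                         se_reduction = NULL, racm_stages = c(4L, 2L),
                         racm_convs = 2L, dffm_kernel = 3L,
                         in_slices = 11L, in_plane = 64L) {
  down_mode <- match.arg(down_mode)
  if (!is.null(preset)) {
    if (!(is.numeric(preset) && length(preset) == 1L && preset %in% 1:6))
      stop("model_config: unknown ablation preset '", preset,
           "'; valid presets are 1 (V-Net), 2 (S3D V-Net), 3 (+DFFM), ",
           "4 (+RACM), 5 (+central pooling), 6 (+SE, full model)")
    s3d_levels <- if (preset >= 2) 5L else integer(0)
    use_dffm <- preset >= 3
    use_racm <- preset >= 4
    down_mode <- if (preset >= 5) "central" else "conv"
    use_se <- preset >= 6
  }
  if (is.null(se_reduction)) se_reduction <- min(16L, as.integer(base_channels))
  levels <- length(enc_convs)
  if (levels != 5L || length(dec_convs) != 4L)
    stop("model_config: expected 5 encoder levels and 4 decoder stages")
  if (length(s3d_levels) && !all(s3d_levels %in% seq_len(levels)))
    stop("model_config: s3d_levels must be a subset of 1..", levels)
  ch <- as.integer(base_channels) * 2L^(0:(levels - 1L))
  dec_ch <- 2L * ch[4:1]
  if (use_se && any(dec_ch %% se_reduction != 0L))
    stop("model_config: se_reduction ", se_reduction,
         " must divide every decoder width (", paste(dec_ch, collapse = ", "), ")")
  if (use_racm && (length(racm_stages) != 2L || racm_stages[1] <= racm_stages[2]))
    stop("model_config: racm_stages must be two decoder levels, deepest first")
  structure(list(
    preset = preset, base_channels = as.integer(base_channels),
    levels = levels, channels = ch,
    enc_convs = as.integer(enc_convs), dec_convs = as.integer(dec_convs),
    kernel = as.integer(kernel), s3d_levels = as.integer(s3d_levels),
    down_mode = down_mode, use_dffm = use_dffm, use_racm = use_racm,
    use_central_pool = identical(down_mode, "central"), use_se = use_se,
    se_reduction = as.integer(se_reduction),
    racm_stages = as.integer(racm_stages), racm_convs = as.integer(racm_convs),
    dffm_kernel = as.integer(dffm_kernel),
    in_slices = as.integer(in_slices), in_plane = as.integer(in_plane)
  ), class = "model_config")
}

# ---- module constructors ---------------------------------------------------

#' Separable-3D convolution block
#'
#' Factorises a `k x k x k` convolution into an intra-slice `(1, k, k)`
#' convolution followed by an inter-slice `(k, 1, 1)` convolution, each with
#' batch normalisation (and a PReLU activation). With `kernel = 3` and equal
#' channel counts this uses 12/27 of the dense kernel's weights.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel kernel extent being factorised.
#' @param bias include convolution biases.
#' @return A module usable with [module_forward()].
#' @export
s3d_block <- function(in_channels, out_channels, kernel = 3L, bias = TRUE) {
  u <- make_conv_unit(in_channels, out_channels, kernel, s3d = TRUE, bias = bias)
  structure(list(unit = u, in_channels = in_channels,
                 out_channels = out_channels), class = "s3d_block")
}

#' Residual convolution block
#'
#' `n_convs` convolution units with an additive shortcut from block input to
#' block output. A single-channel input is tiled across the block width (the
#' V-Net input stage); any other width mismatch is resolved by a learned
#' 1x1x1 projection.
#'
#' @param in_channels,channels input and block width.
#' @param n_convs convolution units in the block.
#' @param kernel kernel extent.
#' @param s3d use separable (S3D) units.
#' @return residual block module.
#' @export
residual_block <- function(in_channels, channels, n_convs, kernel = 5L,
                           s3d = FALSE) {
  units <- lapply(seq_len(n_convs), function(i) {
    make_conv_unit(if (i == 1L) in_channels else channels, channels, kernel,
                   s3d = s3d)
  })
  proj <- NULL
  if (in_channels != channels && in_channels != 1L)
    proj <- layer_conv3d(in_channels, channels, 1L)
  structure(list(units = units, proj = proj, in_channels = in_channels,
                 channels = channels), class = "residual_block")
}

#' Down-transition
#'
#' Halves the in-plane extent and doubles the channel count. Three modes:
#' strided 2x2x2 convolution (`"conv"`, the V-Net baseline), uniform
#' stride-2 max pooling (`"maxpool"`) or centre-weighted pooling
#' (`"central"`), the latter two followed by a channel-doubling 2x2x2
#' stride-1 convolution so all modes carry identical parameter counts.
#' Central pooling falls back to uniform pooling when the plane extent is
#' not divisible by 8 (no integer window partition exists there).
#'
#' @param in_channels input width (output is twice this).
#' @param mode `"conv"`, `"maxpool"` or `"central"`.
#' @return down-transition module.
#' @export
down_transition <- function(in_channels, mode = c("conv", "maxpool", "central")) {
  mode <- match.arg(mode)
  out_ch <- 2L * in_channels
  conv <- if (mode == "conv") {
    layer_conv3d(in_channels, out_ch, c(2L, 2L, 2L), stride = c(2L, 2L, 1L),
                 pad_lo = c(0L, 0L, 1L), pad_hi = c(0L, 0L, 0L))
  } else {
    layer_conv3d(in_channels, out_ch, c(2L, 2L, 2L), stride = c(1L, 1L, 1L),
                 pad_lo = c(1L, 1L, 1L), pad_hi = c(0L, 0L, 0L))
  }
  structure(list(mode = mode, conv = conv, bn = layer_batchnorm(out_ch),
                 act = layer_prelu(out_ch), in_channels = in_channels,
                 out_channels = out_ch), class = "down_transition")
}

#' Up-transition
#'
#' Transposed 2x2x2 convolution doubling the in-plane extent and reducing
#' channels, followed by batch normalisation and PReLU.
#'
#' @param in_channels,out_channels channel counts.
#' @return up-transition module.
#' @export
up_transition <- function(in_channels, out_channels) {
  structure(list(
    deconv = layer_conv3d_transpose(in_channels, out_channels, c(2L, 2L, 2L),
                                    stride = c(2L, 2L, 1L),
                                    pad_lo = c(0L, 0L, 1L),
                                    pad_hi = c(0L, 0L, 0L)),
    bn = layer_batchnorm(out_channels), act = layer_prelu(out_channels)
  ), class = "up_transition")
}

#' Dual-branch feature fusion module (DFFM)
#'
#' Fuses same-level encoder and decoder features: each branch passes a
#' same-padding convolution + BN + PReLU; the encoder branch is additionally
#' max-pooled at stride 1 (same size) to emphasise locally dominant
#' responses; the branches are summed and activated. Output shape equals
#' input shape.
#'
#' @param channels feature width of the level.
#' @param kernel branch convolution kernel extent.
#' @return DFFM module.
#' @export
dffm <- function(channels, kernel = 3L) {
  structure(list(
    enc_unit = make_conv_unit(channels, channels, kernel),
    dec_unit = make_conv_unit(channels, channels, kernel),
    fuse_act = layer_prelu(channels), channels = channels, kernel = kernel
  ), class = "dffm")
}

#' Reverse-attention context module (one unit)
#'
#' Computes attention `A = 1 - sigmoid(coarse_logits)` and returns
#' `f + A * conv(f)` (a jump connection), focusing capacity on regions the
#' coarse prediction has not yet claimed.
#'
#' @param channels feature width.
#' @param n_convs convolution units inside the module.
#' @return RACM unit module.
#' @export
racm_unit <- function(channels, n_convs = 2L) {
  units <- lapply(seq_len(n_convs), function(i)
    make_conv_unit(channels, channels, 3L))
  structure(list(units = units, channels = channels), class = "racm_unit")
}

#' Squeeze-and-excite block
#'
#' Global-average squeeze per channel, two-layer bottleneck (reduction
#' `r`), sigmoid gate, channelwise rescale.
#'
#' @param channels feature width (must be divisible by `reduction`).
#' @param reduction bottleneck reduction ratio.
#' @return SE module.
#' @export
se_block <- function(channels, reduction = 16L) {
  if (channels < reduction || channels %% reduction != 0L)
    stop("se_block: channels (", channels,
         ") must be divisible by reduction (", reduction, ")")
  structure(list(fc1 = layer_dense(channels, channels %/% reduction),
                 fc2 = layer_dense(channels %/% reduction, channels),
                 channels = channels), class = "se_block")
}

# ---- module forward passes -------------------------------------------------

block_forward <- function(mod, x, training, ctx) {
  h <- x
  for (u in mod$units) h <- unit_forward(u, h, training, ctx)
  shortcut <- x
  if (mod$in_channels != mod$channels) {
    shortcut <- if (mod$in_channels == 1L) op_repeat_channels(x, mod$channels)
                else op_conv3d(x, mod$proj, ctx)
  }
  op_add(h, shortcut)
}

down_forward <- function(mod, x, training, ctx) {
  d <- dim(x$value)
  h <- if (mod$mode == "conv") {
    op_conv3d(x, mod$conv, ctx)
  } else {
    p <- if (mod$mode == "central" && d[1] %% 8L == 0L && d[1] == d[2]) {
      op_central_pool(x)
    } else {
      op_maxpool(x, k = c(2L, 2L, 1L), s = c(2L, 2L, 1L))
    }
    op_conv3d(p, mod$conv, ctx)
  }
  op_prelu(op_batchnorm(h, mod$bn, training), mod$act)
}

up_forward <- function(mod, x, training, ctx) {
  op_prelu(op_batchnorm(op_conv3d_transpose(x, mod$deconv, ctx),
                        mod$bn, training), mod$act)
}

dffm_forward <- function(mod, enc, dec, training, ctx) {
  e <- unit_forward(mod$enc_unit, enc, training, ctx)
  e <- op_maxpool(e, k = rep(mod$kernel, 3L), s = c(1L, 1L, 1L), same = TRUE)
  d <- unit_forward(mod$dec_unit, dec, training, ctx)
  op_prelu(op_add(e, d), mod$fuse_act)
}

racm_forward <- function(mod, f, coarse_logits, training, ctx) {
  a <- op_affine(op_sigmoid(coarse_logits), -1, 1)  # reverse attention
  h <- f
  for (u in mod$units) h <- unit_forward(u, h, training, ctx)
  op_add(f, op_mul_gate(h, a))
}

# channel-broadcast multiply by a 1-channel gate
op_mul_gate <- function(a, gate) {
  d <- dim(a$value)
  y <- a$value * gate$value[, , , rep(1L, d[4]), , drop = FALSE]
  new_node(y, list(a, gate), function(g) {
    gx <- g * gate$value[, , , rep(1L, d[4]), , drop = FALSE]
    gg_full <- g * a$value
    gg <- gg_full[, , , 1L, , drop = FALSE]
    if (d[4] > 1L) for (c in 2:d[4]) gg <- gg + gg_full[, , , c, , drop = FALSE]
    list(gx, gg)
  })
}

se_forward <- function(mod, x, training, ctx) {
  s <- op_global_avg_pool(x)
  s <- op_relu_mat(op_dense(s, mod$fc1))
  s <- op_sigmoid_mat(op_dense(s, mod$fc2))
  if (!is.null(ctx)) {
    n <- ncol(s$value)
    ctx$macs <- ctx$macs + (length(mod$fc1$w) + length(mod$fc2$w)) * n
  }
  op_scale_channels(x, s)
}

#' Apply a standalone module to an array
#'
#' Convenience wrapper for applying a single module (from [s3d_block()],
#' [residual_block()], [down_transition()], [dffm()], [racm_unit()],
#' [se_block()], ...) outside a full model. Arrays use the network layout
#' `(C, Z, Y, X)` (a batch dimension of 1 is implied).
#'
#' @param mod module object.
#' @param x input array `(C, Z, Y, X)`.
#' @param ... second input for binary modules: `dec` for `dffm`,
#'   `coarse_logits` for `racm_unit`.
#' @param training run batch norm in training mode.
#' @return output array `(C, Z, Y, X)`.
#' @export
module_forward <- function(mod, x, ..., training = FALSE) {
  xi <- ad_input(czyx_to_net(x))
  extra <- list(...)
  out <- switch(class(mod)[1],
    s3d_block = unit_forward(mod$unit, xi, training, NULL),
    residual_block = block_forward(mod, xi, training, NULL),
    down_transition = down_forward(mod, xi, training, NULL),
    up_transition = up_forward(mod, xi, training, NULL),
    dffm = dffm_forward(mod, xi, ad_input(czyx_to_net(extra[[1]])),
                        training, NULL),
    racm_unit = racm_forward(mod, xi, ad_input(czyx_to_net(extra[[1]])),
                             training, NULL),
    se_block = se_forward(mod, xi, training, NULL),
    stop("module_forward: unsupported module class ", class(mod)[1])
  )
  net_to_czyx(out$value)
}

# (C, Z, Y, X) [+ optional batch] <-> internal (X, Y, Z, C, N)
czyx_to_net <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    y <- aperm(x, c(4, 3, 2, 1))
    dim(y) <- c(d[4], d[3], d[2], d[1], 1L)
    y
  } else if (length(d) == 5L) {
    aperm(x, c(5, 4, 3, 2, 1))
  } else stop("expected a (C, Z, Y, X) array")
}

net_to_czyx <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(5, 4, 3, 2, 1))
  if (d[5] == 1L) { dim(y) <- rev(d)[-1]; y } else y
}

# ---- full model ------------------------------------------------------------

collect_layers <- function(x) {
  if (inherits(x, "nn_layer")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(unclass(x), collect_layers)))
  list()
}

#' Build the segmentation network
#'
#' Assembles the encoder--decoder described by a [model_config()] and
#' initialises all weights (He initialisation; seed via `set.seed()` before
#' calling for reproducibility).
#'
#' @param cfg a [model_config()].
#' @return An object of class `nodseg_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- cfg$channels
  m <- list()
  m$enc <- lapply(1:5, function(l) {
    residual_block(if (l == 1L) 1L else ch[l], ch[l], cfg$enc_convs[l],
                   cfg$kernel, s3d = l %in% cfg$s3d_levels)
  })
  m$down <- lapply(1:4, function(l) down_transition(ch[l], cfg$down_mode))
  m$up <- lapply(4:1, function(j) {
    in_ch <- if (j == 4L) ch[5] else 2L * ch[j + 1L]
    up_transition(in_ch, ch[j])
  })
  names(m$up) <- paste0("d", 4:1)
  m$dec <- lapply(4:1, function(j) {
    residual_block(2L * ch[j], 2L * ch[j], cfg$dec_convs[5L - j], cfg$kernel)
  })
  names(m$dec) <- paste0("d", 4:1)
  if (cfg$use_dffm) m$dffm <- lapply(1:4, function(l) dffm(ch[l], cfg$dffm_kernel))
  if (cfg$use_se)
    m$se <- lapply(4:1, function(j) se_block(2L * ch[j], cfg$se_reduction))
  if (cfg$use_racm) {
    c1 <- 2L * ch[cfg$racm_stages[1]]
    c2 <- 2L * ch[cfg$racm_stages[2]]
    m$racm <- list(
      head0 = layer_conv3d(c1, 1L, 1L),
      unit1 = racm_unit(c1, cfg$racm_convs),
      head1 = layer_conv3d(c1, 1L, 1L),
      unit2 = racm_unit(c2, cfg$racm_convs)
    )
  }
  m$head <- layer_conv3d(2L * ch[1], 1L, 1L)
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$modules <- m
  model$layers <- collect_layers(m)
  class(model) <- "nodseg_model"
  model
}

#' Forward pass
#'
#' @param model a [build_model()] network.
#' @param x input array: `(Z, Y, X)`, `(C, Z, Y, X)` with `C = 1`, or
#'   `(N, C, Z, Y, X)` for a batch.
#' @param stats `"batch"` (default) normalises with the statistics of the
#'   presented input — the better-calibrated choice for the single-volume
#'   inference this network is trained with (instance-normalisation
#'   behaviour) — while `"running"` uses the stored training averages.
#' @return probability array shaped like the input (values in `(0, 1)`).
#' @export
model_predict <- function(model, x, stats = c("batch", "running")) {
  stats <- match.arg(stats)
  res <- model_forward(model, x,
                       training = if (stats == "batch") "batch" else FALSE)
  net_to_czyx(res$probs$value)
}

# Internal forward returning tape nodes (for training) plus the input node.
model_forward <- function(model, x, training = FALSE, ctx = NULL) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(1L, d); d <- dim(x) }
  if (length(d) == 4L) { x <- array(x, c(1L, d)); d <- dim(x) }  # batch of 1
  xi <- ad_input(aperm(x, c(5, 4, 3, 2, 1)))  # (X, Y, Z, C, N)
  mods <- model$modules
  cfg <- model$cfg
  skips <- vector("list", 5L)
  h <- xi
  for (l in 1:5) {
    if (l > 1L) h <- down_forward(mods$down[[l - 1L]], h, training, ctx)
    h <- block_forward(mods$enc[[l]], h, training, ctx)
    skips[[l]] <- h
  }
  dnode <- skips[[5L]]
  p1 <- NULL
  p1_stage <- NA_integer_
  for (j in 4:1) {
    key <- paste0("d", j)
    u <- up_forward(mods$up[[key]], dnode, training, ctx)
    s <- skips[[j]]
    if (cfg$use_dffm) s <- dffm_forward(mods$dffm[[j]], s, u, training, ctx)
    cat_in <- op_concat_channels(u, s)
    b <- block_forward(mods$dec[[key]], cat_in, training, ctx)
    if (cfg$use_se) b <- se_forward(mods$se[[5L - j]], b, training, ctx)
    if (cfg$use_racm && j == cfg$racm_stages[1]) {
      p0 <- op_conv3d(b, mods$racm$head0, ctx)
      b <- racm_forward(mods$racm$unit1, b, p0, training, ctx)
      p1 <- op_conv3d(b, mods$racm$head1, ctx)
      p1_stage <- j
    }
    if (cfg$use_racm && j == cfg$racm_stages[2]) {
      gate <- p1
      for (k in seq_len(p1_stage - j)) gate <- op_upsample_nearest2(gate)
      b <- racm_forward(mods$racm$unit2, b, gate, training, ctx)
    }
    dnode <- b
  }
  logits <- op_conv3d(dnode, mods$head, ctx)
  probs <- op_sigmoid(logits)
  list(probs = probs, input = xi)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] network.
#' @return integer: total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, layer_param_count, numeric(1)))
}

#' Count multiply--accumulate operations of one forward pass
#'
#' Counts the multiplications performed by convolution, transposed
#' convolution and dense layers (the standard MAC-counting convention;
#' normalisation, activations and pooling contribute none).
#'
#' @param model a [build_model()] network.
#' @param input_shape `(C, Z, Y, X)` input geometry (default the 11-slice
#'   64 x 64 ROI).
#' @return total MACs (numeric, typically reported as GMAC = 1e9 MACs).
#' @export
count_macs <- function(model, input_shape = c(1L, 11L, 64L, 64L)) {
  ctx <- new.env(parent = emptyenv())
  ctx$macs <- 0
  x <- array(0, dim = input_shape)
  invisible(model_forward(model, x, training = FALSE, ctx = ctx))
  ctx$macs
}

#' Architecture report
#'
#' @param cfg a [model_config()].
#' @return list with the parameter count (M), GMACs at the standard input,
#'   and the central-pooling window layouts in use.
#' @export
report_arch <- function(cfg) {
  model <- build_model(cfg)
  planes <- cfg$in_plane / 2^(0:3)
  parts <- lapply(planes[planes %% 8 == 0], function(q) build_partition(q))
  list(
    preset = cfg$preset,
    parameters = count_parameters(model),
    parameters_m = count_parameters(model) / 1e6,
    gmacs = count_macs(model, c(1L, cfg$in_slices, cfg$in_plane, cfg$in_plane)) / 1e9,
    pooling_layouts = lapply(parts, function(p)
      list(Q = p$axis_length, counts = as.list(p$counts),
           layout = p$layout))
  )
}
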