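#' Training configuration
#'
#' Defaults follow the training protocol used for the full LUNA16-scale
#' experiments: Adam at an initial learning rate of 3e-4, batch size 8, up
#' to 200 epochs, with the learning rate decaying by 1% every 30 epochs
#' (a step schedule), and the compound Dice + BCE loss with equal weights.
#'
#' @param lr0 initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param lr_decay_every epochs between learning-rate steps.
#' @param lr_decay_factor multiplicative decay per step (0.99 = "decreases
#'   by 1%").
#' @param seed RNG seed governing weight init and data order.
#' @param loss a [loss_config()].
#' @param folds number of cross-validation folds.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr0 = 3e-4, batch_size = 8L, max_epochs = 200L,
                         lr_decay_every = 30L, lr_decay_factor = 0.99,
                         seed = 1L, loss = loss_config(), folds = 10L) {
  if (lr0 <= 0) stop("train_config: lr0 must be positive")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (folds < 2L) stop("train_config: folds must be >= 2")
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed),
                 loss = loss, folds = as.integer(folds)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' `lr = lr0 * factor^floor(epoch / every)`: piecewise constant,
#' non-increasing, with breakpoints at multiples of `lr_decay_every`.
#'
#' @param epoch epoch index (0-based).
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$lr_decay_factor^(floor(epoch / cfg$lr_decay_every))
}

#' Assign cross-validation folds
#'
#' Honours a pre-existing `subset` column (the official LUNA16 split) when
#' present; otherwise partitions series into `k` near-equal groups at
#' random (seeded). Samples are grouped by `series` so no series ever spans
#' folds.
#'
#' @param sample_index data.frame with a `series` column (and optionally
#'   `subset`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of 0-based fold ids, one per row.
#' @export
make_folds <- function(sample_index, k = 10L, seed = 1L) {
  stopifnot(is.data.frame(sample_index), "series" %in% names(sample_index))
  if ("subset" %in% names(sample_index)) {
    f <- as.integer(sample_index$subset)
    if (any(is.na(f) | f < 0L)) stop("make_folds: invalid `subset` column")
    return(f)
  }
  series <- unique(sample_index$series)
  if (length(series) < k)
    stop("make_folds: ", length(series), " series cannot fill ", k, " folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(series)
  fold_of_series <- stats::setNames(rep_len(0:(k - 1L), length(series)),
                                    perm)
  unname(fold_of_series[as.character(sample_index$series)])
}

# ---- optimiser -------------------------------------------------------------

zero_grads <- function(model) {
  for (layer in model$layers)
    for (nm in layer$param_names)
      assign(paste0("g", nm), get(nm, envir = layer) * 0, envir = layer)
  invisible(NULL)
}

adam_step <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (layer in model$layers) {
    for (nm in layer$param_names) {
      g <- get(paste0("g", nm), envir = layer)
      mkey <- paste0("adam_m_", nm)
      vkey <- paste0("adam_v_", nm)
      m <- if (is.null(layer[[mkey]])) g * 0 else layer[[mkey]]
      v <- if (is.null(layer[[vkey]])) g * 0 else layer[[vkey]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      assign(mkey, m, envir = layer)
      assign(vkey, v, envir = layer)
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- get(nm, envir = layer) - lr * mhat / (sqrt(vhat) + eps)
      assign(nm, p, envir = layer)
    }
  }
  invisible(NULL)
}

# Stack roi_samples into network batches: (X, Y, Z, 1, N) arrays.
rois_to_batch <- function(samples) {
  imgs <- lapply(samples, function(s) aperm(s$image, c(3, 2, 1)))
  d <- dim(imgs[[1]])
  x <- array(0, dim = c(d, 1L, length(samples)))
  y <- array(0, dim = c(d, 1L, length(samples)))
  for (i in seq_along(samples)) {
    x[, , , 1L, i] <- imgs[[i]]
    y[, , , 1L, i] <- aperm(samples[[i]]$mask, c(3, 2, 1))
  }
  list(x = x, y = y)
}

soft_dsc <- function(p, y, eps = 1e-5) {
  (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

#' Train a model on one set of ROI samples
#'
#' Minibatch Adam on the compound Dice + BCE loss. Fully seeded: weight
#' initialisation (when `model` is `NULL`), sample order and every other
#' source of randomness derive from `train_cfg$seed`, so identical calls
#' produce identical loss curves.
#'
#' @param samples list of [roi_sample()] (the training split).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param max_steps optional cap on optimiser steps (otherwise
#'   `max_epochs` sweeps).
#' @param stop_dsc optional early-stop threshold on training soft-DSC.
#' @param eval_every steps between full training-set soft-DSC evaluations
#'   when `stop_dsc` is set.
#' @param model optionally continue training an existing model.
#' @param verbose print progress every 25 steps.
#' @return list with `model`, `log` (data.frame: step, epoch, lr, loss,
#'   soft_dsc), and `best` (weights snapshot is the final state; the row of
#'   the best loss is recorded).
#' @export
train_fold <- function(samples, model_cfg, train_cfg = train_config(),
                       max_steps = NULL, stop_dsc = NULL, eval_every = 20L,
                       model = NULL, verbose = FALSE) {
  if (!length(samples)) stop("train_fold: empty training split")
  set.seed(train_cfg$seed)
  if (is.null(model)) model <- build_model(model_cfg)
  n <- length(samples)
  bs <- min(train_cfg$batch_size, n)
  steps_per_epoch <- max(1L, n %/% bs)
  total_steps <- if (is.null(max_steps))
    train_cfg$max_epochs * steps_per_epoch else as.integer(max_steps)
  order_pool <- integer(0)
  log <- vector("list", total_steps)
  step <- 0L
  while (step < total_steps) {
    step <- step + 1L
    epoch <- (step - 1L) %/% steps_per_epoch
    lr <- lr_schedule(epoch, train_cfg)
    if (length(order_pool) < bs) order_pool <- c(order_pool, sample(n))
    idx <- order_pool[seq_len(bs)]
    order_pool <- order_pool[-seq_len(bs)]
    batch <- rois_to_batch(samples[idx])
    zero_grads(model)
    fwd <- model_forward(model, from_batch_input(batch$x), training = TRUE)
    loss_node <- op_bcedice(fwd$probs, batch$y, train_cfg$loss)
    loss <- loss_node$value
    if (!is.finite(loss))
      stop("train_fold: non-finite loss at step ", step,
           " (lr = ", lr, "); aborting")
    sdsc <- soft_dsc(fwd$probs$value, batch$y)
    ad_backward(loss_node)
    adam_step(model, lr, step)
    log[[step]] <- data.frame(step = step, epoch = epoch, lr = lr,
                              loss = loss, soft_dsc = sdsc)
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %4d  loss %.4f  soft-DSC %.4f", step, loss, sdsc))
    if (!is.null(stop_dsc) && step %% eval_every == 0L) {
      full <- evaluate_soft_dsc(model, samples)
      if (verbose) message(sprintf("step %4d  training soft-DSC %.4f", step, full))
      if (full >= stop_dsc) break
    }
  }
  log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  list(model = model, log = log, best = log[which.min(log$loss), ])
}

from_batch_input <- function(x) {
  # x already (X, Y, Z, 1, N): convert to the (N, C, Z, Y, X) user layout
  aperm(x, c(5, 4, 3, 2, 1))
}

# Mean compound loss over a sample set at the current weights (per-sample
# batch statistics, matching the training-time metric).
evaluate_loss <- function(model, samples, loss_cfg = loss_config()) {
  vals <- vapply(samples, function(s) {
    p <- model_predict(model, array(s$image, c(1L, dim(s$image))))
    bcedice_loss(as.vector(p), as.vector(s$mask * 1), loss_cfg)
  }, numeric(1))
  mean(vals)
}

evaluate_soft_dsc <- function(model, samples) {
  vals <- vapply(samples, function(s) {
    p <- model_predict(model, array(s$image, c(1L, dim(s$image))))
    soft_dsc(p, array(s$mask, c(1L, dim(s$mask))))
  }, numeric(1))
  mean(vals)
}

#' Segment one ROI with a trained model
#'
#' Forward pass in evaluation mode, thresholded at `threshold`.
#'
#' @param model trained [build_model()] network.
#' @param roi a [roi_sample()] (its mask is ignored).
#' @param threshold probability cut for the binary mask.
#' @return binary array shaped like `roi$image`.
#' @export
predict_case <- function(model, roi, threshold = 0.5) {
  stopifnot(inherits(roi, "roi_sample"))
  p <- model_predict(model, array(roi$image, c(1L, dim(roi$image))))
  out <- (p >= threshold) * 1L
  dim(out) <- dim(roi$image)
  out
}

#' k-fold cross-validation
#'
#' Trains one model per fold on the out-of-fold samples and evaluates
#' DSC/OE on the held-out fold; reports per-fold results and the overall
#' case-weighted mean +/- SD.
#'
#' @param samples list of [roi_sample()].
#' @param fold_ids integer fold id per sample (e.g. from [make_folds()]).
#' @param model_cfg,train_cfg configurations.
#' @param max_steps optional per-fold step cap (for reduced-scale runs).
#' @param predict_fn predictor `function(model, roi) -> binary array`;
#'   override for testing the aggregation independently of training.
#' @param verbose print fold progress.
#' @return list of class `cv_result` with `folds` (list of per-fold
#'   results) and `summary` (data.frame).
#' @export
cross_validate <- function(samples, fold_ids, model_cfg,
                           train_cfg = train_config(), max_steps = NULL,
                           predict_fn = predict_case, verbose = FALSE) {
  stopifnot(length(samples) == length(fold_ids))
  folds <- sort(unique(fold_ids))
  fold_results <- lapply(folds, function(f) {
    train_idx <- which(fold_ids != f)
    test_idx <- which(fold_ids == f)
    if (!length(train_idx)) stop("cross_validate: fold ", f, " has no training data")
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    fit <- train_fold(samples[train_idx], model_cfg, cfg_f, max_steps = max_steps)
    dscs <- numeric(length(test_idx))
    oes <- numeric(length(test_idx))
    for (i in seq_along(test_idx)) {
      s <- samples[[test_idx[i]]]
      pred <- predict_fn(fit$model, s)
      dscs[i] <- dsc(pred, s$mask)
      oes[i] <- oe(pred, s$mask)
    }
    if (verbose)
      message(sprintf("fold %d: mDSC %.4f  mOE %.4f (n=%d)", f, mean(dscs),
                      mean(oes), length(test_idx)))
    list(fold_index = f, case_dsc = dscs, case_oe = oes,
         mean_dsc = mean(dscs), mean_oe = mean(oes), sd_dsc = sd(dscs),
         n_cases = length(test_idx),
         test_ids = vapply(samples[test_idx], function(s) s$source_id, ""),
         train_ids = vapply(samples[train_idx], function(s) s$source_id, ""))
  })
  all_dsc <- unlist(lapply(fold_results, `[[`, "case_dsc"))
  all_oe <- unlist(lapply(fold_results, `[[`, "case_oe"))
  summary <- data.frame(
    fold = c(vapply(fold_results, `[[`, numeric(1), "fold_index"), NA),
    mDSC = c(vapply(fold_results, `[[`, numeric(1), "mean_dsc"), mean(all_dsc)),
    mOE = c(vapply(fold_results, `[[`, numeric(1), "mean_oe"), mean(all_oe)),
    n = c(vapply(fold_results, `[[`, numeric(1), "n_cases"), length(all_dsc))
  )
  structure(list(folds = fold_results, summary = summary,
                 mean_dsc = mean(all_dsc), mean_oe = mean(all_oe),
                 sd_dsc = sd(all_dsc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mDSC %.4f +/- %.4f, mOE %.4f\n",
              length(x$folds), x$mean_dsc, x$sd_dsc, x$mean_oe))
  invisible(x)
}
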