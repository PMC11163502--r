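#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|) = 2TP / (2TP + FP + FN)} between two
#' binary masks. By convention two empty masks have DSC 1.
#'
#' @param pred_mask,gt_mask binary arrays of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred_mask, gt_mask) {
  check_mask_pair(pred_mask, gt_mask)
  tp <- sum(pred_mask == 1 & gt_mask == 1)
  denom <- sum(pred_mask == 1) + sum(gt_mask == 1)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Overlapping error
#'
#' \eqn{OE = 1 - |A \cap B| / |A \cup B| = 1 - TP / (TP + FP + FN)}, i.e.
#' one minus the Jaccard index. Two empty masks have OE 0.
#'
#' @inheritParams dsc
#' @return OE in `[0, 1]`.
#' @export
oe <- function(pred_mask, gt_mask) {
  check_mask_pair(pred_mask, gt_mask)
  tp <- sum(pred_mask == 1 & gt_mask == 1)
  uni <- sum(pred_mask == 1 | gt_mask == 1)
  if (uni == 0) return(0)
  1 - tp / uni
}

check_mask_pair <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mask shapes differ")
  if (!all(a %in% c(0, 1, TRUE, FALSE)) || !all(b %in% c(0, 1, TRUE, FALSE)))
    stop("masks must be binary")
  invisible(NULL)
}

#' Loss configuration
#'
#' @param a mixing weight of the Dice term in the compound loss, in `[0,1]`
#'   (default 0.5, the weighting that performed best in the ablation of the
#'   compound loss).
#' @param wp positive-class weight of the binary cross-entropy term
#'   (default 1: the nodule-centred crops already limit the
#'   foreground/background imbalance).
#' @return list of class `loss_config`.
#' @export
loss_config <- function(a = 0.5, wp = 1.0) {
  if (!is.finite(a) || a < 0 || a > 1)
    stop("loss_config: `a` must lie in [0, 1]")
  if (!is.finite(wp) || wp <= 0)
    stop("loss_config: `wp` must be positive")
  structure(list(a = a, wp = wp), class = "loss_config")
}

#' Soft Dice loss
#'
#' \eqn{L_{dice} = 1 - DSC_{soft}} where the soft DSC uses elementwise
#' products as the intersection:
#' \eqn{(2 \sum p g + \epsilon) / (\sum p + \sum g + \epsilon)}.
#'
#' @param pred_probs numeric array of probabilities in `[0, 1]`.
#' @param gt_mask binary array, same shape.
#' @param eps additive smoothing in numerator and denominator.
#' @return loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, gt_mask, eps = 1e-5) {
  if (!identical(dim(pred_probs) %||% length(pred_probs),
                 dim(gt_mask) %||% length(gt_mask)))
    stop("dice_loss: shape mismatch")
  if (any(pred_probs < 0 | pred_probs > 1))
    stop("dice_loss: predictions must lie in [0, 1]")
  1 - (2 * sum(pred_probs * gt_mask) + eps) /
    (sum(pred_probs) + sum(gt_mask) + eps)
}

#' Weighted binary cross-entropy loss
#'
#' Voxel mean of \eqn{-[w_p\, y \log x + (1 - y) \log(1 - x)]} with
#' probabilities clipped to `[delta, 1 - delta]`.
#'
#' @inheritParams dice_loss
#' @param cfg [loss_config()] providing the positive-class weight `wp`.
#' @param delta clipping bound for numerical stability.
#' @return non-negative loss.
#' @export
bce_loss <- function(pred_probs, gt_mask, cfg = loss_config(), delta = 1e-7) {
  if (!identical(dim(pred_probs) %||% length(pred_probs),
                 dim(gt_mask) %||% length(gt_mask)))
    stop("bce_loss: shape mismatch")
  x <- pmin(pmax(pred_probs, delta), 1 - delta)
  y <- as.numeric(gt_mask)
  -mean(cfg$wp * y * log(x) + (1 - y) * log(1 - x))
}

#' Compound Dice + BCE loss
#'
#' \eqn{L = a\,L_{dice} + (1 - a)\,L_{bce}}; with the default `a = 0.5`
#' both terms contribute equally.
#'
#' @inheritParams bce_loss
#' @return non-negative loss.
#' @export
bcedice_loss <- function(pred_probs, gt_mask, cfg = loss_config()) {
  if (!inherits(cfg, "loss_config")) stop("bcedice_loss: cfg must be a loss_config")
  cfg$a * dice_loss(pred_probs, gt_mask) +
    (1 - cfg$a) * bce_loss(pred_probs, gt_mask, cfg)
}

#' Two-sample t-test on fold-level scores
#'
#' Compares per-fold mean scores (e.g. mDSC over 10 cross-validation folds)
#' of two models with an unpaired, two-sided, pooled-variance t-test
#' (`df = n_a + n_b - 2`), and reports the per-group mean and SD alongside.
#'
#' @param folds_a,folds_b numeric vectors of per-fold scores (>= 2 each).
#' @return list of class `stats_result` with `t`, `p`, `df` and `groups`.
#' @export
t_test_compare <- function(folds_a, folds_b) {
  if (length(folds_a) < 2L || length(folds_b) < 2L)
    stop("t_test_compare: need at least 2 values per group")
  ht <- t.test(folds_a, folds_b, var.equal = TRUE)
  structure(list(
    t = unname(ht$statistic), p = unname(ht$p.value),
    df = unname(ht$parameter),
    groups = data.frame(
      group = c("a", "b"),
      mean = c(mean(folds_a), mean(folds_b)),
      sd = c(sd(folds_a), sd(folds_b)),
      n = c(length(folds_a), length(folds_b))
    )
  ), class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  cat(sprintf("  a: %.4f +/- %.4f (n=%d)   b: %.4f +/- %.4f (n=%d)\n",
              x$groups$mean[1], x$groups$sd[1], x$groups$n[1],
              x$groups$mean[2], x$groups$sd[2], x$groups$n[2]))
  invisible(x)
}
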