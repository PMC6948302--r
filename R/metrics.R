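#' Region-based soft Dice loss
#'
#' Computes `1 - (2 * sum(p * g) + eps) / (sum(p^2 + g^2) + eps)` over all
#' pixels of one image block, where `p` are predicted foreground
#' probabilities and `g` the binary ground truth. The loss is 0 for a
#' perfect hard prediction, 1 when prediction and truth are disjoint and
#' non-empty, and differentiable in `p`. The background contributes nothing
#' to the numerator and no `g^2` term, so the loss is driven by the
#' foreground region; setting `masked_background = TRUE` additionally
#' restricts the `p^2` denominator term to ground-truth foreground pixels
#' (an alternative reading of the background-exclusion rule, off by
#' default).
#'
#' @param pred Probability array with values in `[0, 1]`.
#' @param truth Congruent binary ground-truth array.
#' @param eps Smoothing constant added to numerator and denominator so the
#'   empty-vs-empty case is well defined (loss 0).
#' @param masked_background Restrict the `p^2` term to foreground pixels.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1e-7, masked_background = FALSE) {
  check_pair(pred, truth, pred_prob = TRUE)
  num <- 2 * sum(pred * truth)
  den <- if (masked_background) sum((pred^2 + truth^2) * (truth > 0))
         else sum(pred^2) + sum(truth^2)
  1 - (num + eps) / (den + eps)
}

# Analytic gradient of dice_loss with respect to pred.
dice_loss_grad <- function(pred, truth, eps = 1e-7,
                           masked_background = FALSE) {
  num <- 2 * sum(pred * truth) + eps
  if (masked_background) {
    fg <- truth > 0
    den <- sum((pred^2 + truth^2) * fg) + eps
    dnum <- 2 * truth
    dden <- 2 * pred * fg
  } else {
    den <- sum(pred^2) + sum(truth^2) + eps
    dnum <- 2 * truth
    dden <- 2 * pred
  }
  (num * dden - den * dnum) / den^2
}

check_pair <- function(pred, truth, pred_prob = FALSE) {
  if (!all(dim2(pred) == dim2(truth)))
    ms_stop("msunet_congruence_error",
            "prediction and truth shapes differ")
  if (!all(truth %in% c(0, 1)))
    ms_stop("msunet_label_error", "truth mask must be strictly binary")
  if (pred_prob) {
    if (min(pred) < 0 || max(pred) > 1)
      ms_stop("msunet_label_error",
              "predicted probabilities must lie in [0, 1]")
  } else if (!all(pred %in% c(0, 1))) {
    ms_stop("msunet_label_error", "prediction mask must be strictly binary")
  }
  invisible(TRUE)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Pixel-wise confusion counts between binary masks
#'
#' @param pred Binary predicted mask.
#' @param truth Congruent binary ground-truth mask.
#' @return List of class `ms_overlap_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
overlap_counts <- function(pred, truth) {
  check_pair(pred, truth)
  p <- pred > 0; t <- truth > 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "ms_overlap_counts")
}

#' Overlap metrics from confusion counts
#'
#' Computes DSC `= 2TP / (2TP + FP + FN)`, sensitivity `= TP / (TP + FN)`,
#' positive predictive value `= TP / (TP + FP)` and IoU
#' `= TP / (TP + FP + FN)`. Degenerate denominators follow the bounded
#' convention: a metric whose reference set is empty scores 1 when the
#' other set is also empty and 0 otherwise.
#'
#' @param counts An [overlap_counts()] result, or a binary prediction mask
#'   (with `truth` supplied).
#' @param truth Optional ground-truth mask when `counts` is a mask.
#' @return List of class `ms_metrics_report` with `dsc`, `sen`, `ppv`,
#'   `iou` and the `counts`.
#' @export
compute_metrics <- function(counts, truth = NULL) {
  if (!inherits(counts, "ms_overlap_counts")) {
    if (is.null(truth))
      ms_stop("msunet_config_error",
              "supply overlap counts, or a prediction mask plus truth")
    counts <- overlap_counts(counts, truth)
  }
  with(counts, {
    if (any(c(tp, fp, fn, tn) < 0))
      ms_stop("msunet_validation_error", "counts must be nonnegative")
    ratio <- function(num, den, empty_ok) if (den == 0) empty_ok else num / den
    both_empty <- as.numeric(tp + fp + fn == 0)
    structure(list(
      dsc = ratio(2 * tp, 2 * tp + fp + fn, both_empty),
      sen = ratio(tp, tp + fn, as.numeric(fp == 0)),
      ppv = ratio(tp, tp + fp, as.numeric(fn == 0)),
      iou = ratio(tp, tp + fp + fn, both_empty),
      counts = list(tp = tp, fp = fp, fn = fn, tn = tn)),
      class = "ms_metrics_report")
  })
}

#' @export
print.ms_metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  SEN %.4f  PPV %.4f  IoU %.4f (TP %d FP %d FN %d)\n",
              x$dsc, x$sen, x$ppv, x$iou, x$counts$tp, x$counts$fp,
              x$counts$fn))
  invisible(x)
}

#' Per-case and aggregate evaluation table
#'
#' @param preds List of binary prediction masks.
#' @param truths List of congruent ground-truth masks.
#' @return Data frame with one row per case plus a `"mean"` aggregate row,
#'   columns `case`, `dsc`, `sen`, `ppv`, `iou`.
#' @export
evaluate_pairs <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  rows <- lapply(seq_along(preds), function(i) {
    m <- compute_metrics(overlap_counts(preds[[i]], truths[[i]]))
    data.frame(case = as.character(i), dsc = m$dsc, sen = m$sen,
               ppv = m$ppv, iou = m$iou)
  })
  tab <- do.call(rbind, rows)
  agg <- data.frame(case = "mean", dsc = mean(tab$dsc), sen = mean(tab$sen),
                    ppv = mean(tab$ppv), iou = mean(tab$iou))
  rbind(tab, agg)
}
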