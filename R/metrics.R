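#' Pixel-wise confusion counts
#'
#' @param pred,truth binary masks of equal shape.
#' @return list of class \code{confusion_counts} with \code{tp}, \code{fp},
#'   \code{fn}, \code{tn} (pixel tallies summing to the image size).
#' @export
confusion_counts <- function(pred, truth) {
  dp <- dim(pred); dt <- dim(truth)
  if (!identical(dp, dt))
    stop("shape mismatch: pred ", paste(dp, collapse = "x"), " vs truth ",
         paste(dt, collapse = "x"))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  p <- pred == 1; t <- truth == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Dice similarity coefficient from confusion counts
#'
#' \eqn{2TP / (2TP + FP + FN)}; when both masks are empty the convention is
#' perfect agreement (1.0).
#'
#' @param c a \code{\link{confusion_counts}}.
#' @return Dice in [0, 1].
#' @export
dice_coefficient <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1.0)
  2 * c$tp / den
}

#' Jaccard index (IoU) from confusion counts
#'
#' \eqn{TP / (TP + FP + FN)}; both-empty convention 1.0.
#'
#' @inheritParams dice_coefficient
#' @return IoU in [0, 1].
#' @export
jaccard_index <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1.0)
  c$tp / den
}

#' Convert Jaccard/IoU to Dice
#'
#' Uses the identity \eqn{D = 2J / (1 + J)}.
#'
#' @param j IoU value in [0, 1].
#' @return the corresponding Dice value.
#' @export
dice_from_jaccard <- function(j) 2 * j / (1 + j)

#' Precision and recall from confusion counts
#'
#' \eqn{TP/(TP+FP)} and \eqn{TP/(TP+FN)}; a zero denominator yields
#' \code{NA} (undefined), never 0.
#'
#' @inheritParams dice_coefficient
#' @return named numeric vector \code{c(precision, recall)}.
#' @export
precision_recall <- function(c) {
  pr <- if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp)
  re <- if (c$tp + c$fn == 0) NA_real_ else c$tp / (c$tp + c$fn)
  c(precision = pr, recall = re)
}

#' Mean absolute error between a probability map and a binary mask
#'
#' @param prob probability map in [0, 1].
#' @param truth binary mask of the same shape.
#' @return mean of \eqn{|y_i - \hat y_i|} over all pixels.
#' @export
mean_absolute_error <- function(prob, truth) {
  if (!identical(dim(prob), dim(truth)))
    stop("shape mismatch between prob and truth")
  mean(abs(truth - prob))
}

# Foreground pixels with at least one background 4-neighbor (the image border
# counts as background), as (row, col) coordinates.
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  inner <- pad[2:(H + 1), 2:(W + 1)] == 1
  nb_bg <- (pad[1:H, 2:(W + 1)] == 0) | (pad[3:(H + 2), 2:(W + 1)] == 0) |
    (pad[2:(H + 1), 1:W] == 0) | (pad[2:(H + 1), 3:(W + 2)] == 0)
  which(inner & nb_bg, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' 95th percentile of the pooled directed boundary-to-boundary Euclidean
#' distances between the two masks (both directions). Boundaries are
#' foreground pixels with a background 4-neighbor; distances come from an
#' exact Euclidean distance transform. Identical masks give 0; an empty mask
#' gives \code{NA}.
#'
#' @param pred,truth binary masks of equal shape.
#' @return HD95 in pixels, or \code{NA} if either mask is empty.
#' @export
hd95 <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between pred and truth")
  if (sum(pred) == 0 || sum(truth) == 0) return(NA_real_)
  bp <- boundary_pixels(pred); bt <- boundary_pixels(truth)
  dist_to <- function(bnd) {
    # distance to the nearest pixel of `bnd`: distmap of its complement
    img <- matrix(1, nrow(pred), ncol(pred))
    img[bnd] <- 0
    EBImage::imageData(EBImage::distmap(EBImage::Image(img), metric = "euclidean"))
  }
  dt_truth <- dist_to(bt)
  dt_pred <- dist_to(bp)
  d <- c(dt_truth[bp], dt_pred[bt])
  unname(stats::quantile(d, 0.95, type = 7))
}

#' Pixel-wise ROC AUC
#'
#' Area under the ROC curve over pixel thresholds, computed as the
#' Mann--Whitney rank statistic with midrank tie handling.
#'
#' @param prob probability map.
#' @param truth binary mask of the same shape; must contain both classes,
#'   otherwise \code{NA} is returned.
#' @return AUC in [0, 1] or \code{NA}.
#' @export
auc_roc <- function(prob, truth) {
  if (!identical(dim(prob), dim(truth)))
    stop("shape mismatch between prob and truth")
  pos <- truth == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(as.numeric(prob), ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum p t + s) / (\sum p + \sum t + s)} with smoothing \eqn{s};
#' differentiable in the probabilities and the primary training loss for
#' imbalanced segmentation.
#'
#' @param prob probability map (or batch) in [0, 1].
#' @param truth binary mask of the same shape.
#' @param smooth smoothing constant \eqn{s}.
#' @return loss value in [0, 1].
#' @export
dice_loss <- function(prob, truth, smooth = 1) {
  if (!identical(dim(prob), dim(truth)))
    stop("shape mismatch between prob and truth")
  inter <- sum(prob * truth)
  1 - (2 * inter + smooth) / (sum(prob) + sum(truth) + smooth)
}

# Gradient of the soft Dice loss w.r.t. prob (same shape as prob).
dice_loss_grad <- function(prob, truth, smooth = 1) {
  inter <- sum(prob * truth)
  den <- sum(prob) + sum(truth) + smooth
  -(2 * truth * den - (2 * inter + smooth)) / den^2
}

#' Evaluate one prediction against ground truth
#'
#' Binarizes the probability map at \code{threshold}, computes all overlap
#' metrics from the confusion counts, plus MAE, HD95 and AUC.
#'
#' @param prob probability map.
#' @param truth binary mask.
#' @param threshold binarization cut (default 0.5, matching the mask
#'   standardization convention).
#' @param sample_id optional identifier carried into the row.
#' @return one-row data frame: dice, iou, precision, recall, mae, hd95, auc.
#' @export
evaluate_prediction <- function(prob, truth, threshold = 0.5,
                                sample_id = NA_character_) {
  pred <- (prob > threshold) + 0
  cc <- confusion_counts(pred, truth)
  pr <- precision_recall(cc)
  data.frame(sample_id = sample_id,
             dice = dice_coefficient(cc),
             iou = jaccard_index(cc),
             precision = unname(pr["precision"]),
             recall = unname(pr["recall"]),
             mae = mean_absolute_error(prob, truth),
             hd95 = hd95(pred, truth),
             auc = auc_roc(prob, truth),
             stringsAsFactors = FALSE)
}

#' Evaluate a model over a dataset
#'
#' @param model a \code{segmentation_model}.
#' @param dataset list of preprocessed image samples.
#' @param threshold binarization cut.
#' @return data frame with one \code{\link{evaluate_prediction}} row per
#'   sample.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  rows <- lapply(dataset, function(s) {
    p <- predict(model, s, type = "prob")
    evaluate_prediction(p, s$mask, threshold, s$sample_id)
  })
  do.call(rbind, rows)
}
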