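check_binary_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
}

#' Dice similarity coefficient
#'
#' Overlap statistic `2|A n B| / (|A| + |B|)` between two binary masks.
#' When both masks are empty the result is 1 (perfect agreement on
#' absence).
#'
#' @param pred,gt binary matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coef <- function(pred, gt) {
  check_binary_pair(pred, gt)
  sa <- sum(pred); sb <- sum(gt)
  if (sa + sb == 0) return(1)
  2 * sum(pred * gt) / (sa + sb)
}

#' Intersection-over-Union (Jaccard index)
#'
#' `|A n B| / |A u B|`; both-empty masks score 1. Related to Dice by
#' `D = 2J / (1 + J)`.
#'
#' @inheritParams dice_coef
#' @return scalar in `[0, 1]`.
#' @export
iou_coef <- function(pred, gt) {
  check_binary_pair(pred, gt)
  inter <- sum(pred * gt)
  uni <- sum(pred) + sum(gt) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Pixel-level accuracy
#'
#' Proportion of pixels classified identically in the two masks.
#'
#' @inheritParams dice_coef
#' @return scalar in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, gt) {
  check_binary_pair(pred, gt)
  mean(pred == gt)
}

#' Symmetric Hausdorff distance between two binary masks
#'
#' The maximum of the two directed Hausdorff distances between the
#' positive-pixel coordinate sets (Euclidean, in pixels). Defined only
#' when both masks contain non-zero segmentation; otherwise returns
#' `NA_real_` (the undefined sentinel, excluded from aggregation).
#'
#' @inheritParams dice_coef
#' @return distance in pixels, or `NA_real_` when either mask is empty.
#' @export
hausdorff_distance <- function(pred, gt) {
  check_binary_pair(pred, gt)
  A <- which(pred == 1, arr.ind = TRUE)
  B <- which(gt == 1, arr.ind = TRUE)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  directed <- function(P, Q) {
    # max over P of min distance to Q, chunked to bound memory
    best <- 0
    step <- 2048L
    for (s in seq(1, nrow(P), by = step)) {
      idx <- s:min(s + step - 1L, nrow(P))
      d2 <- outer(P[idx, 1], Q[, 1], "-")^2 + outer(P[idx, 2], Q[, 2], "-")^2
      best <- max(best, sqrt(max(apply(d2, 1, min))))
    }
    best
  }
  max(directed(A, B), directed(B, A))
}

#' Per-image metric bundle
#'
#' Computes Dice, IoU, pixel accuracy and (when defined) the symmetric
#' Hausdorff distance for one predicted/ground-truth mask pair.
#'
#' @inheritParams dice_coef
#' @return list with `dice`, `iou`, `pixel_accuracy`, `hausdorff`.
#' @export
metric_bundle <- function(pred, gt) {
  list(dice = dice_coef(pred, gt), iou = iou_coef(pred, gt),
       pixel_accuracy = pixel_accuracy(pred, gt),
       hausdorff = hausdorff_distance(pred, gt))
}
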