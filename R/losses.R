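#' Composite loss configuration
#'
#' The training loss is `mix_focal * focal + mix_tversky * tversky`.
#' Focal loss down-weights easy pixels via the `(1 - p_t)^gamma`
#' modulating factor; Tversky loss generalizes soft Dice with asymmetric
#' false-positive (`tversky_alpha`) and false-negative (`tversky_beta`)
#' penalties. Defaults use the standard focal parameters (gamma 2,
#' alpha 0.25) and a sensitivity-oriented Tversky weighting (0.3 / 0.7)
#' that penalizes missed lesion pixels more heavily; both terms enter the
#' composite with unit weight.
#'
#' @param focal_gamma focusing exponent, >= 0.
#' @param focal_alpha positive-class balance weight in (0, 1).
#' @param tversky_alpha weight on false positives.
#' @param tversky_beta weight on false negatives.
#' @param mix_focal,mix_tversky non-negative mixing weights (not both 0).
#' @param smooth_eps numerical smoothing / probability-clipping constant.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(focal_gamma = 2, focal_alpha = 0.25,
                        tversky_alpha = 0.3, tversky_beta = 0.7,
                        mix_focal = 1, mix_tversky = 1,
                        smooth_eps = 1e-6) {
  stopifnot(focal_gamma >= 0, focal_alpha > 0, focal_alpha < 1,
            mix_focal >= 0, mix_tversky >= 0)
  if (mix_focal == 0 && mix_tversky == 0) {
    stop("mix weights must not both be zero", call. = FALSE)
  }
  if (tversky_alpha + tversky_beta <= 0) {
    stop("tversky_alpha + tversky_beta must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "loss_config")
}

check_shapes <- function(prob, gt) {
  if (!identical(dim(prob), dim(gt))) {
    stop("probability and ground-truth shapes differ", call. = FALSE)
  }
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t * (1 - p_t)^gamma * log(p_t)` where
#' `p_t` is the predicted probability of the true class and `alpha_t` is
#' `focal_alpha` on positive pixels and `1 - focal_alpha` on negatives.
#' Probabilities are clipped to `[eps, 1 - eps]` before the log.
#'
#' @param prob probability raster in (0, 1).
#' @param gt binary ground-truth raster of the same shape.
#' @param config a [loss_config()].
#' @return non-negative scalar.
#' @export
focal_loss <- function(prob, gt, config = loss_config()) {
  check_shapes(prob, gt)
  eps <- config$smooth_eps
  p <- pmin(pmax(prob, eps), 1 - eps)
  pt <- gt * p + (1 - gt) * (1 - p)
  at <- gt * config$focal_alpha + (1 - gt) * (1 - config$focal_alpha)
  mean(-at * (1 - pt)^config$focal_gamma * log(pt))
}

# d(focal)/d(prob), mean-over-pixels convention.
focal_loss_grad <- function(prob, gt, config = loss_config()) {
  eps <- config$smooth_eps
  p <- pmin(pmax(prob, eps), 1 - eps)
  g <- config$focal_gamma
  pt <- gt * p + (1 - gt) * (1 - p)
  at <- gt * config$focal_alpha + (1 - gt) * (1 - config$focal_alpha)
  # dL/dpt, then chain through dpt/dp = +/-1
  dpt <- at * (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt)
  dpt <- dpt * (2 * gt - 1)
  dpt / length(prob)
}

#' Tversky loss
#'
#' `1 - (TP + eps) / (TP + alpha * FP + beta * FN + eps)` with soft counts
#' `TP = sum(p * g)`, `FP = sum(p * (1 - g))`, `FN = sum((1 - p) * g)`.
#' With `alpha = beta = 0.5` this is the soft Dice loss.
#'
#' @inheritParams focal_loss
#' @return scalar in `[0, 1]`.
#' @export
tversky_loss <- function(prob, gt, config = loss_config()) {
  check_shapes(prob, gt)
  tp <- sum(prob * gt)
  fp <- sum(prob * (1 - gt))
  fn <- sum((1 - prob) * gt)
  eps <- config$smooth_eps
  1 - (tp + eps) / (tp + config$tversky_alpha * fp +
                    config$tversky_beta * fn + eps)
}

tversky_loss_grad <- function(prob, gt, config = loss_config()) {
  tp <- sum(prob * gt)
  fp <- sum(prob * (1 - gt))
  fn <- sum((1 - prob) * gt)
  eps <- config$smooth_eps
  a <- config$tversky_alpha; b <- config$tversky_beta
  den <- tp + a * fp + b * fn + eps
  num <- tp + eps
  # d tp/dp = g ; d fp/dp = 1 - g ; d fn/dp = -g
  dden <- gt + a * (1 - gt) - b * gt
  -(gt * den - num * dden) / den^2
}

#' Composite focal + Tversky loss
#'
#' @inheritParams focal_loss
#' @return `mix_focal * focal_loss + mix_tversky * tversky_loss`.
#' @export
composite_loss <- function(prob, gt, config = loss_config()) {
  config$mix_focal * focal_loss(prob, gt, config) +
    config$mix_tversky * tversky_loss(prob, gt, config)
}

composite_loss_grad <- function(prob, gt, config = loss_config()) {
  config$mix_focal * focal_loss_grad(prob, gt, config) +
    config$mix_tversky * tversky_loss_grad(prob, gt, config)
}
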