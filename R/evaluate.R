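#' Detection decision from an IoU value
#'
#' A lesion counts as detected when the image-level IoU is strictly
#' greater than the threshold (default 0.10).
#'
#' @param iou_value IoU in `[0, 1]` (vectorized).
#' @param threshold detection threshold.
#' @return logical vector.
#' @export
detect_lesion <- function(iou_value, threshold = 0.10) {
  iou_value > threshold
}

#' Evaluate a model on a test set
#'
#' Produces one evaluation record per image: predictions are binarized at
#' 0.5, overlap metrics computed against the binary ground truth, the
#' Hausdorff distance left undefined when either mask is empty, and the
#' detection flag derived from the strict IoU rule. The recorded lesion
#' area uses the native-resolution mask area when available (attribute or
#' field `lesion_area_native`), falling back to the model-resolution
#' area; `area_basis` selects the behavior.
#'
#' @param model a `unet_model`.
#' @param pairs non-empty list of model-resolution [image_pair()]s.
#' @param detection_threshold IoU detection threshold.
#' @param bounds `c(small_upper, medium_upper)` pixel-area category
#'   bounds.
#' @param area_basis `"native"` or `"model"`.
#' @return data.frame of class `eval_records` with columns id, dice, iou,
#'   pixel_accuracy, hausdorff, lesion_area, detected, size_category.
#' @export
evaluate_test_set <- function(model, pairs, detection_threshold = 0.10,
                              bounds = c(500, 1500),
                              area_basis = c("native", "model")) {
  if (length(pairs) == 0) stop("empty test set", call. = FALSE)
  area_basis <- match.arg(area_basis)
  rows <- lapply(pairs, function(pair) {
    pr <- predict_mask(model, pair$image, threshold = 0.5)
    gm <- binarize_mask(pair$mask + 0, 0.5)
    mb <- metric_bundle(pr$mask, gm)
    area <- if (area_basis == "native") {
      an <- attr(pair, "lesion_area_native")
      if (is.null(an)) an <- pair$lesion_area_native
      an
    } else {
      sum(gm)
    }
    data.frame(id = pair$id, dice = mb$dice, iou = mb$iou,
               pixel_accuracy = mb$pixel_accuracy, hausdorff = mb$hausdorff,
               lesion_area = area,
               detected = detect_lesion(mb$iou, detection_threshold),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$size_category <- categorize_area(rec$lesion_area, bounds)
  class(rec) <- c("eval_records", "data.frame")
  rec
}

#' Construct evaluation records directly
#'
#' Assembles an `eval_records` table from per-image metric vectors, for
#' use when predictions come from outside [evaluate_test_set()] (or when
#' reproducing published count tables).
#'
#' @param id identifiers.
#' @param iou per-image IoU values.
#' @param dice per-image Dice values.
#' @param lesion_area per-image lesion pixel areas.
#' @param pixel_acc,hausdorff optional metric vectors.
#' @param detection_threshold IoU detection threshold.
#' @param bounds category bounds.
#' @return data.frame of class `eval_records`.
#' @export
eval_records <- function(id, iou, dice, lesion_area, pixel_acc = NA_real_,
                         hausdorff = NA_real_, detection_threshold = 0.10,
                         bounds = c(500, 1500)) {
  rec <- data.frame(id = as.character(id), dice = dice, iou = iou,
                    pixel_accuracy = pixel_acc, hausdorff = hausdorff,
                    lesion_area = lesion_area,
                    detected = detect_lesion(iou, detection_threshold),
                    stringsAsFactors = FALSE)
  rec$size_category <- categorize_area(rec$lesion_area, bounds)
  class(rec) <- c("eval_records", "data.frame")
  rec
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on k - 1 degrees of freedom. When all values are
#' identical (degenerate tie correction) H is defined as 0 with p = 1.
#'
#' @param groups list of >= 2 numeric vectors (>= 3 values in total).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("each group needs >= 1 value", call. = FALSE)
  x <- unlist(groups)
  n <- length(x)
  if (n < 3) stop("need >= 3 values in total", call. = FALSE)
  r <- rank(x)
  grp <- rep(seq_along(groups), sizes)
  rs <- tapply(r, grp, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) {
    h <- 0; p <- 1
  } else {
    h <- h / tie_corr
    p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  }
  list(H = unname(h), p = unname(p), df = length(groups) - 1)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction and continuity correction (the standard large-sample
#' formulation).
#'
#' @param x,y numeric vectors.
#' @return list with `W` (rank-sum statistic of `x`), `p`.
#' @export
mann_whitney_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  n <- nx + ny
  mu <- nx * ny / 2
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = w, p = 1))
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
  list(W = unname(w), p = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5))
}

#' Compare lesion sizes of missed versus detected lesions
#'
#' Reports mean lesion areas per group with a two-sided Mann-Whitney
#' rank test (and a Welch t test as a secondary line). When one group is
#' empty, means are reported and the tests are undefined.
#'
#' @param records an `eval_records` data frame.
#' @return list with `mean_missed`, `mean_detected`, `p_rank`, `W`,
#'   `p_welch`.
#' @export
compare_missed_vs_detected <- function(records) {
  a_missed <- records$lesion_area[!records$detected]
  a_det <- records$lesion_area[records$detected]
  out <- list(mean_missed = if (length(a_missed)) mean(a_missed) else NA_real_,
              mean_detected = if (length(a_det)) mean(a_det) else NA_real_,
              W = NA_real_, p_rank = NA_real_, p_welch = NA_real_)
  if (length(a_missed) > 0 && length(a_det) > 0) {
    mw <- mann_whitney_test(a_missed, a_det)
    out$W <- mw$W
    out$p_rank <- mw$p
    if (length(a_missed) > 1 && length(a_det) > 1 &&
        (sd(a_missed) > 0 || sd(a_det) > 0)) {
      out$p_welch <- t.test(a_missed, a_det)$p.value
    }
  }
  out
}

#' Correlation between lesion size and segmentation quality
#'
#' Computed among detected lesions only.
#'
#' @param records an `eval_records` data frame.
#' @param metric `"dice"` or `"iou"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient, or `NA_real_` when fewer than 3
#'   detected records or constant inputs.
#' @export
size_quality_correlation <- function(records, metric = c("dice", "iou"),
                                     method = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  det <- records[records$detected, ]
  if (nrow(det) < 3) return(NA_real_)
  if (sd(det$lesion_area) == 0 || sd(det[[metric]]) == 0) return(NA_real_)
  cor(det$lesion_area, det[[metric]], method = method)
}

#' Size-stratified detection and segmentation report
#'
#' Stratifies evaluation records into small/medium/large categories
#' (small: area < `bounds[1]`; medium: `bounds[1]` <= area <=
#' `bounds[2]`; large: area > `bounds[2]`), computing per-category
#' counts, detection rates (per cent, full precision kept internally;
#' rounding to one decimal belongs to the presentation layer), mean
#' lesion areas, metric summaries among detected lesions, Kruskal-Wallis
#' group tests for Dice and IoU among detected, the missed-vs-detected
#' size comparison, size-quality correlations among detected, and overall
#' means that include missed lesions with their actual (typically zero)
#' scores.
#'
#' @param records an `eval_records` data frame.
#' @param bounds category bounds `c(500, 1500)`.
#' @return object of class `stratified_report`.
#' @export
stratify_records <- function(records, bounds = c(500, 1500)) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  records$size_category <- categorize_area(records$lesion_area, bounds)
  cats <- c("small", "medium", "large")
  per_cat <- do.call(rbind, lapply(cats, function(cc) {
    sub <- records[records$size_category == cc, ]
    det <- sub[sub$detected, ]
    data.frame(
      category = cc,
      n = nrow(sub),
      n_detected = nrow(det),
      n_missed = nrow(sub) - nrow(det),
      detection_rate_pct = if (nrow(sub)) 100 * nrow(det) / nrow(sub)
                           else NA_real_,
      mean_area = if (nrow(sub)) mean(sub$lesion_area) else NA_real_,
      mean_dice_detected = if (nrow(det)) mean(det$dice) else NA_real_,
      sd_dice_detected = if (nrow(det) > 1) sd(det$dice) else NA_real_,
      mean_iou_detected = if (nrow(det)) mean(det$iou) else NA_real_,
      sd_iou_detected = if (nrow(det) > 1) sd(det$iou) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  det <- records[records$detected, ]
  kw_dice <- kw_iou <- NULL
  nonempty <- cats[vapply(cats, function(cc) {
    sum(det$size_category == cc) > 0
  }, logical(1))]
  if (length(nonempty) >= 2 && nrow(det) >= 3) {
    kw_dice <- kruskal_wallis_test(
      lapply(nonempty, function(cc) det$dice[det$size_category == cc]))
    kw_iou <- kruskal_wallis_test(
      lapply(nonempty, function(cc) det$iou[det$size_category == cc]))
  }
  structure(list(
    per_category = per_cat,
    n_total = nrow(records),
    n_detected = sum(records$detected),
    n_missed = sum(!records$detected),
    overall_detection_rate_pct = 100 * mean(records$detected),
    missed_share_pct = 100 * mean(!records$detected),
    overall_mean_dice = mean(records$dice),
    overall_mean_iou = mean(records$iou),
    overall_mean_pixel_accuracy = mean(records$pixel_accuracy),
    mean_hausdorff_defined = if (any(!is.na(records$hausdorff)))
      mean(records$hausdorff, na.rm = TRUE) else NA_real_,
    n_hausdorff_undefined = sum(is.na(records$hausdorff)),
    kruskal_dice = kw_dice,
    kruskal_iou = kw_iou,
    missed_vs_detected = compare_missed_vs_detected(records),
    correlation_dice = size_quality_correlation(records, "dice"),
    correlation_iou = size_quality_correlation(records, "iou"),
    bounds = bounds
  ), class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat(sprintf("Size-stratified report (n = %d, detected %d, missed %d)\n",
              x$n_total, x$n_detected, x$n_missed))
  pc <- x$per_category
  pc$detection_rate_pct <- round(pc$detection_rate_pct, 1)
  print(pc, row.names = FALSE)
  cat(sprintf("Overall detection rate: %.1f%%; missed share: %.1f%%\n",
              x$overall_detection_rate_pct, x$missed_share_pct))
  if (!is.null(x$kruskal_dice)) {
    cat(sprintf("Kruskal-Wallis Dice: H = %.2f, p = %.4g\n",
                x$kruskal_dice$H, x$kruskal_dice$p))
    cat(sprintf("Kruskal-Wallis IoU:  H = %.2f, p = %.4g\n",
                x$kruskal_iou$H, x$kruskal_iou$p))
  }
  invisible(x)
}

#' Resolution-budget analysis
#'
#' Quantifies the information loss of downsampling: the linear fold
#' reduction `native_side / target_side` and the equivalent lesion area
#' after downsampling, `lesion_area_native * (target_side /
#' native_side)^2`.
#'
#' @param native_side native resolution (pixels per side).
#' @param target_side model input resolution.
#' @param lesion_area_native lesion pixel area at native resolution.
#' @return list with `fold_reduction` and `equivalent_area`.
#' @export
resolution_analysis <- function(native_side, target_side, lesion_area_native) {
  stopifnot(native_side > 0, target_side > 0, all(lesion_area_native > 0))
  list(fold_reduction = native_side / target_side,
       equivalent_area = lesion_area_native * (target_side / native_side)^2)
}
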