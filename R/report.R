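#' Write results-style tables and a JSON report
#'
#' Emits `overall_metrics.csv` (mean/median/SD of each metric),
#' `detection_by_size.csv` (per-category counts and detection rates,
#' rates rounded to one decimal) and `metrics_by_size.csv` (per-category
#' metric means +/- SD among detected lesions plus the Kruskal-Wallis
#' statistics), together with `report.json` holding the full-precision
#' report for machine consumption.
#'
#' @param records an `eval_records` data frame.
#' @param report the matching `stratified_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(records, report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summarize <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), median = median(v), sd = if (length(v) > 1) sd(v) else NA)
  }
  overall <- data.frame(
    metric = c("dice", "iou", "pixel_accuracy", "hausdorff"),
    rbind(summarize(records$dice), summarize(records$iou),
          summarize(records$pixel_accuracy), summarize(records$hausdorff)))
  write.csv(overall, file.path(dir, "overall_metrics.csv"), row.names = FALSE)

  det <- report$per_category
  det$detection_rate_pct <- round(det$detection_rate_pct, 1)
  overall_row <- data.frame(
    category = "overall", n = report$n_total, n_detected = report$n_detected,
    n_missed = report$n_missed,
    detection_rate_pct = round(report$overall_detection_rate_pct, 1),
    mean_area = mean(records$lesion_area),
    mean_dice_detected = NA, sd_dice_detected = NA,
    mean_iou_detected = NA, sd_iou_detected = NA)
  write.csv(rbind(det, overall_row), file.path(dir, "detection_by_size.csv"),
            row.names = FALSE)

  kw <- function(k, f) if (is.null(k)) NA_real_ else k[[f]]
  m3 <- data.frame(
    metric = c("dice", "iou"),
    small = c(det$mean_dice_detected[1], det$mean_iou_detected[1]),
    medium = c(det$mean_dice_detected[2], det$mean_iou_detected[2]),
    large = c(det$mean_dice_detected[3], det$mean_iou_detected[3]),
    H = c(kw(report$kruskal_dice, "H"), kw(report$kruskal_iou, "H")),
    p = c(kw(report$kruskal_dice, "p"), kw(report$kruskal_iou, "p")))
  write.csv(m3, file.path(dir, "metrics_by_size.csv"), row.names = FALSE)

  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}

#' Write per-image metric rows as CSV
#'
#' Columns: id, dice, iou, pixel_acc, hausdorff_or_NA, lesion_area,
#' detected, size_category.
#'
#' @param records an `eval_records` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

mask_boundary <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  mask == 1 & er == 0
}

#' Write a prediction-versus-ground-truth overlay PNG
#'
#' Renders the grayscale image with the ground-truth boundary in green
#' and the predicted boundary in red.
#'
#' @param pair an [image_pair()] (ground truth).
#' @param pred_mask binary predicted mask of the same shape.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(pair, pred_mask, path) {
  img <- clamp01(pair$image)
  rgb <- array(rep(img, 3), c(dim(img), 3))
  gtb <- mask_boundary(binarize_mask(pair$mask + 0, 0.5))
  prb <- mask_boundary(binarize_mask(pred_mask + 0, 0.5))
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  g[gtb] <- 1; r[gtb] <- 0; b[gtb] <- 0
  r[prb] <- 1; g[prb] <- pmin(g[prb], 0.2); b[prb] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}
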