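#' Preprocessing configuration
#'
#' Defaults follow the conventional mammography preprocessing recipe:
#' min-max normalization to `[0, 1]`, CLAHE with clip limit 2.0 on an
#' 8 x 8 tile grid, resizing to 224 x 224 model resolution, and mask
#' binarization at 0.5.
#'
#' @param clahe_clip_limit positive clip limit (relative).
#' @param clahe_tile_grid integer tile-grid size g, meaning a g x g grid.
#' @param target_side model input resolution in pixels.
#' @param mask_threshold binarization threshold in (0, 1).
#' @param resize_method `"bilinear"` (default) or `"area"`
#'   (box-filter antialiasing before bilinear subsampling).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2.0, clahe_tile_grid = 8L,
                              target_side = 224L, mask_threshold = 0.5,
                              resize_method = c("bilinear", "area")) {
  stopifnot(clahe_clip_limit > 0, clahe_tile_grid >= 1,
            mask_threshold > 0, mask_threshold < 1)
  structure(list(
    clahe_clip_limit = clahe_clip_limit,
    clahe_tile_grid = as.integer(clahe_tile_grid),
    target_side = as.integer(target_side),
    mask_threshold = mask_threshold,
    resize_method = match.arg(resize_method)
  ), class = "preprocess_config")
}

# CLAHE wrapper: pads the image (edge replication) to dimensions divisible
# by the tile grid, applies contrast-limited adaptive histogram
# equalization, and crops back.
clahe_padded <- function(image, grid, limit) {
  h <- nrow(image); w <- ncol(image)
  ph <- ceiling(h / grid) * grid
  pw <- ceiling(w / grid) * grid
  x <- image
  if (ph > h) x <- rbind(x, x[rep(h, ph - h), , drop = FALSE])
  if (pw > w) x <- cbind(x, x[, rep(w, pw - w), drop = FALSE])
  y <- EBImage::clahe(x, nx = grid, ny = grid, limit = limit)
  y <- as.matrix(y)[seq_len(h), seq_len(w), drop = FALSE]
  y
}

#' Normalize intensities to `[0, 1]` and apply CLAHE
#'
#' Converts the raster to floating point, min-max normalizes to `[0, 1]`,
#' then applies Contrast Limited Adaptive Histogram Equalization with the
#' configured clip limit and tile grid. A constant (zero-range) image is
#' returned as all zeros with a warning rather than dividing by zero.
#'
#' @param image numeric matrix with finite intensities.
#' @param config a [preprocess_config()].
#' @return numeric matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_and_enhance <- function(image, config = preprocess_config()) {
  if (!is.matrix(image) || length(image) == 0) {
    stop("image must be a non-empty matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) stop("image has non-finite values", call. = FALSE)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: returning all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  x <- (image - rng[1]) / diff(rng)
  y <- clahe_padded(x, config$clahe_tile_grid, config$clahe_clip_limit)
  clamp01(y)
}

#' Binarize a real-valued mask
#'
#' Output is 1 where the input is strictly greater than `threshold`, else
#' 0. The strict inequality keeps interpolation-induced exact-threshold
#' halos out of the lesion. Idempotent on already-binary masks (for any
#' threshold in (0, 1)).
#'
#' @param mask numeric matrix with finite values.
#' @param threshold scalar threshold.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_mask <- function(mask, threshold = 0.5) {
  if (!all(is.finite(mask))) stop("mask has non-finite values", call. = FALSE)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask > threshold] <- 1L
  out
}

resize_gray <- function(image, target_side, method = "bilinear") {
  if (method == "area" && nrow(image) > target_side) {
    f <- floor(nrow(image) / target_side)
    if (f >= 2) {
      k <- matrix(1 / f^2, f, f)
      image <- as.matrix(EBImage::filter2(image, k))
    }
  }
  as.matrix(EBImage::resize(image, w = target_side, h = target_side))
}

#' Resize an image/mask pair to model resolution
#'
#' The image is resampled with bilinear interpolation (optionally with
#' area antialiasing); the mask is resampled the same way and then
#' re-binarized at 0.5 so the output mask is strictly binary. Native and
#' resized lesion areas and the linear reduction factor are recorded as
#' attributes.
#'
#' @param pair an [image_pair()].
#' @param target_side target resolution (>= 32). Upsampling is allowed.
#' @param method `"bilinear"` or `"area"`.
#' @return an [image_pair()] at `target_side`, with attributes
#'   `lesion_area_resized`, `lesion_area_native` and `linear_reduction`.
#' @export
resize_pair <- function(pair, target_side = 224, method = "bilinear") {
  stopifnot(inherits(pair, "image_pair"), target_side >= 32)
  img <- resize_gray(pair$image, target_side, method)
  msk <- binarize_mask(resize_gray(pair$mask + 0, target_side, method), 0.5)
  out <- image_pair(pair$id, clamp01(img), msk,
                    native_side = pair$native_side)
  attr(out, "lesion_area_native") <- pair$lesion_area_native
  attr(out, "lesion_area_resized") <- sum(msk)
  attr(out, "linear_reduction") <- pair$native_side / target_side
  out
}

#' Dataset sparsity statistics
#'
#' Characterizes segmentation sparsity: total pixels, positive (lesion)
#' pixels, lesion-to-background ratio and the per-image area list.
#'
#' @param pairs non-empty list of [image_pair()] objects.
#' @return list with `total_pixels`, `positive_pixels`,
#'   `lesion_background_ratio` (positive / (total - positive)) and
#'   `per_image_areas`.
#' @export
dataset_stats <- function(pairs) {
  if (length(pairs) == 0) stop("empty pair list", call. = FALSE)
  areas <- vapply(pairs, function(p) sum(p$mask), numeric(1))
  total <- sum(vapply(pairs, function(p) length(p$mask), numeric(1)))
  pos <- sum(areas)
  list(total_pixels = total, positive_pixels = pos,
       lesion_background_ratio = if (total == pos) Inf else pos / (total - pos),
       per_image_areas = areas)
}
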