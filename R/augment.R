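#' Augmentation configuration
#'
#' Minor, lesion-aware augmentation: random rotation (0-10 degrees by
#' default), horizontal flipping, elastic deformation, jittered
#' re-application of CLAHE (photometric), small random zoom (0-12%) and a
#' background-preserving random crop constrained to keep the lesion
#' visible. Each transform is applied independently with probability
#' `prob`.
#'
#' @param rotation_deg_max maximal rotation angle in degrees; the angle is
#'   drawn uniformly from `[0, rotation_deg_max]`.
#' @param hflip enable horizontal flipping.
#' @param elastic enable elastic deformation.
#' @param elastic_alpha displacement amplitude in pixels at a 224-pixel
#'   image side (scaled linearly with image size).
#' @param elastic_sigma Gaussian smoothing sigma of the displacement
#'   field, in pixels at a 224-pixel side.
#' @param zoom_max_frac maximal zoom-in fraction; the zoom factor is drawn
#'   from `[0, zoom_max_frac]`.
#' @param clahe_jitter enable randomized CLAHE re-application with a
#'   jittered clip limit (photometric augmentation; image only).
#' @param lesion_preserving_crop enable the random crop that keeps the
#'   lesion bounding box inside the cropped window.
#' @param crop_min_frac smallest crop side as a fraction of the image side.
#' @param prob per-transform application probability in `[0, 1]`.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(rotation_deg_max = 10, hflip = TRUE,
                           elastic = TRUE, elastic_alpha = 30,
                           elastic_sigma = 6, zoom_max_frac = 0.12,
                           clahe_jitter = TRUE,
                           lesion_preserving_crop = TRUE,
                           crop_min_frac = 0.85, prob = 0.5) {
  stopifnot(rotation_deg_max >= 0, zoom_max_frac >= 0,
            prob >= 0, prob <= 1, crop_min_frac > 0, crop_min_frac <= 1)
  structure(as.list(environment()), class = "augment_config")
}

# Vectorized bilinear sampling of `img` at (continuous, 1-based) source
# coordinates; out-of-range coordinates read as 0 (background).
bilinear_sample <- function(img, si, sj) {
  h <- nrow(img); w <- ncol(img)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  get <- function(i, j) {
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    v <- numeric(length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  v <- (1 - fi) * (1 - fj) * get(i0, j0) +
       fi * (1 - fj) * get(i0 + 1, j0) +
       (1 - fi) * fj * get(i0, j0 + 1) +
       fi * fj * get(i0 + 1, j0 + 1)
  matrix(v, h, w)
}

# Apply a geometric source-coordinate map to both rasters of a pair.
warp_pair <- function(img, msk, si, sj) {
  list(image = bilinear_sample(img, si, sj),
       mask = bilinear_sample(msk, si, sj))
}

grid_coords <- function(side) {
  list(i = matrix(rep(seq_len(side), side), side),
       j = matrix(rep(seq_len(side), each = side), side))
}

#' Augment an image/mask pair
#'
#' Applies the configured stochastic transforms, with every geometric
#' transform applied identically to image and mask (the mask is carried as
#' a continuous raster through the interpolating transforms and
#' re-binarized at 0.5 at the end). When `lesion_preserving_crop` is on
#' and the input mask is non-empty, the output mask is guaranteed
#' non-empty: draws that would lose the lesion are re-drawn (up to 10
#' times; the identity transform is the final fallback).
#'
#' @param pair an [image_pair()].
#' @param config an [augment_config()].
#' @param seed optional integer; when given, the augmentation is a pure
#'   function of (pair, config, seed).
#' @return an augmented [image_pair()].
#' @export
augment_pair <- function(pair, config = augment_config(), seed = NULL) {
  stopifnot(inherits(pair, "image_pair"), inherits(config, "augment_config"))
  if (!is.null(seed)) {
    return(with_seed(seed, augment_pair(pair, config, seed = NULL)))
  }
  guard <- config$lesion_preserving_crop && sum(pair$mask) > 0
  for (attempt in 1:10) {
    out <- augment_once(pair, config)
    if (!guard || sum(out$mask) > 0) return(out)
  }
  pair
}

augment_once <- function(pair, config) {
  img <- pair$image
  msk <- pair$mask + 0
  side <- nrow(img)
  p <- config$prob
  g <- grid_coords(side)
  ctr <- (side + 1) / 2

  if (config$rotation_deg_max > 0 && runif(1) < p) {
    th <- runif(1, 0, config$rotation_deg_max) * pi / 180
    di <- g$i - ctr; dj <- g$j - ctr
    si <- cos(th) * di - sin(th) * dj + ctr
    sj <- sin(th) * di + cos(th) * dj + ctr
    w <- warp_pair(img, msk, si, sj); img <- w$image; msk <- w$mask
  }
  if (config$hflip && runif(1) < p) {
    img <- img[, rev(seq_len(side))]
    msk <- msk[, rev(seq_len(side))]
  }
  if (config$elastic && runif(1) < p) {
    scale <- side / 224
    sig <- config$elastic_sigma * scale
    alpha <- config$elastic_alpha * scale
    dfield <- function() {
      d <- EBImage::gblur(matrix(runif(side^2, -1, 1), side), sigma = sig)
      alpha * d / max(abs(d))
    }
    si <- g$i + dfield(); sj <- g$j + dfield()
    w <- warp_pair(img, msk, si, sj); img <- w$image; msk <- w$mask
  }
  if (config$zoom_max_frac > 0 && runif(1) < p) {
    s <- 1 + runif(1, 0, config$zoom_max_frac)
    si <- (g$i - ctr) / s + ctr
    sj <- (g$j - ctr) / s + ctr
    w <- warp_pair(img, msk, si, sj); img <- w$image; msk <- w$mask
  }
  if (config$lesion_preserving_crop && runif(1) < p) {
    cs <- round(side * runif(1, config$crop_min_frac, 1))
    bb <- lesion_bbox(binarize_mask(msk, 0.5))
    if (is.null(bb) || (bb$rmax - bb$rmin < cs && bb$cmax - bb$cmin < cs)) {
      rlo <- if (is.null(bb)) c(1, side - cs + 1) else
        c(max(1, bb$rmax - cs + 1), min(side - cs + 1, bb$rmin))
      clo <- if (is.null(bb)) c(1, side - cs + 1) else
        c(max(1, bb$cmax - cs + 1), min(side - cs + 1, bb$cmin))
      if (rlo[1] <= rlo[2] && clo[1] <= clo[2]) {
        r0 <- round(runif(1, rlo[1], rlo[2]))
        c0 <- round(runif(1, clo[1], clo[2]))
        imgc <- img[r0:(r0 + cs - 1), c0:(c0 + cs - 1)]
        mskc <- msk[r0:(r0 + cs - 1), c0:(c0 + cs - 1)]
        img <- resize_gray(imgc, side)
        msk <- resize_gray(mskc, side)
      }
    }
  }
  if (config$clahe_jitter && runif(1) < p) {
    limit <- runif(1, 1.5, 2.5)
    if (diff(range(img)) > 0) img <- clahe_padded(clamp01(img), 8L, limit)
  }
  image_pair(pair$id, clamp01(img), binarize_mask(msk, 0.5),
             native_side = pair$native_side)
}
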