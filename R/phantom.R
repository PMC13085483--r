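#' Configuration for a synthetic mammographic phantom
#'
#' Describes one phantom image: a half-elliptical breast-shaped foreground
#' with spatially correlated parenchymal texture against a dark background,
#' plus zero or more smooth irregular lesions of controlled pixel area.
#' The phantom is a stress fixture for segmentation pipelines, not a
#' physically realistic X-ray simulation.
#'
#' @param image_side native resolution in pixels (square image), >= 256.
#' @param lesion_areas numeric vector of target lesion areas in pixels
#'   (one entry per lesion); may be empty for a lesion-free phantom.
#' @param lesion_contrast relative intensity uplift of lesions over local
#'   tissue, in `[0, 1]`. May be a scalar or one value per lesion.
#' @param texture_scale spatial correlation length of the parenchymal
#'   texture, in pixels; defaults to 1/12 of the image side so the
#'   texture is smoother than typical lesions at any rendering
#'   resolution.
#' @param texture_amplitude intensity standard deviation of the texture.
#' @param background_level mean intensity of breast tissue in `[0, 1]`.
#' @param seed integer; identical configs (including seed) produce
#'   bit-identical phantoms.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_side = 1024, lesion_areas = numeric(0),
                           lesion_contrast = 0.2,
                           texture_scale = image_side / 12,
                           texture_amplitude = 0.03,
                           background_level = 0.45, seed = 1L) {
  stopifnot_scalar(image_side, "image_side")
  if (image_side < 256) stop("image_side must be >= 256", call. = FALSE)
  if (length(lesion_areas) && any(lesion_areas < 1)) {
    stop("all lesion_areas must be >= 1", call. = FALSE)
  }
  if (any(lesion_contrast < 0) || any(lesion_contrast > 1)) {
    stop("lesion_contrast must lie in [0, 1]", call. = FALSE)
  }
  if (length(lesion_contrast) > 1 &&
      length(lesion_contrast) != length(lesion_areas)) {
    stop("lesion_contrast must be scalar or one value per lesion",
         call. = FALSE)
  }
  structure(list(
    image_side = as.integer(image_side),
    lesion_areas = as.numeric(lesion_areas),
    lesion_contrast = as.numeric(lesion_contrast),
    texture_scale = as.numeric(texture_scale),
    texture_amplitude = as.numeric(texture_amplitude),
    background_level = as.numeric(background_level),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Construct an image/mask pair
#'
#' Container coupling one grayscale raster (intensities in `[0, 1]`) with
#' its aligned binary lesion mask.
#'
#' @param id character identifier.
#' @param image numeric matrix, intensities in `[0, 1]`.
#' @param mask integer/numeric matrix of the same shape with values in
#'   `{0, 1}`.
#' @param native_side native resolution the pair was rendered/acquired at.
#' @return an object of class `image_pair` with fields `id`, `image`,
#'   `mask`, `native_side` and `lesion_area_native` (count of 1-pixels).
#' @export
image_pair <- function(id, image, mask, native_side = nrow(image)) {
  if (!is.matrix(image) || !is.matrix(mask)) {
    stop("image and mask must be matrices", call. = FALSE)
  }
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  structure(list(
    id = as.character(id),
    image = image,
    mask = mask,
    native_side = as.integer(native_side),
    lesion_area_native = sum(mask)
  ), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair '%s'> %dx%d, lesion area %d px\n", x$id,
              nrow(x$image), ncol(x$image), as.integer(x$lesion_area_native)))
  invisible(x)
}

# Smoothed-noise texture field with unit standard deviation.
texture_field <- function(side, scale) {
  n1 <- matrix(rnorm(side^2), side, side)
  n2 <- matrix(rnorm(side^2), side, side)
  t1 <- EBImage::gblur(n1, sigma = scale)
  t2 <- EBImage::gblur(n2, sigma = max(1, scale / 4))
  f <- 0.7 * t1 / stats::sd(t1) + 0.3 * t2 / stats::sd(t2)
  f / stats::sd(f)
}

# Render one irregular blob mask of approximately `area` pixels centered at
# (ci, cj). The boundary radius is modulated by low-frequency harmonics.
# Returns a list(rows, cols) of mask pixel indices.
render_blob <- function(side, ci, cj, area) {
  r0 <- sqrt(area / pi)
  k <- 2:5
  amp <- runif(4, 0, 0.12)
  phi <- runif(4, 0, 2 * pi)
  for (iter in 1:4) {
    rmax <- r0 * (1 + sum(amp)) + 1
    i0 <- max(1, floor(ci - rmax)); i1 <- min(side, ceiling(ci + rmax))
    j0 <- max(1, floor(cj - rmax)); j1 <- min(side, ceiling(cj + rmax))
    ii <- i0:i1; jj <- j0:j1
    di <- outer(ii - ci, rep(1, length(jj)))
    dj <- outer(rep(1, length(ii)), jj - cj)
    rr <- sqrt(di^2 + dj^2)
    th <- atan2(dj, di)
    rb <- r0 * (1 + amp[1] * cos(k[1] * th + phi[1]) +
                    amp[2] * cos(k[2] * th + phi[2]) +
                    amp[3] * cos(k[3] * th + phi[3]) +
                    amp[4] * cos(k[4] * th + phi[4]))
    inside <- rr <= rb
    realized <- sum(inside)
    if (realized > 0 && abs(realized - area) / area <= 0.10) break
    r0 <- r0 * sqrt(area / max(realized, 1))
  }
  w <- which(inside, arr.ind = TRUE)
  list(rows = ii[w[, 1]], cols = jj[w[, 2]],
       win = c(i0, i1, j0, j1), inside = inside)
}

#' Generate one synthetic phantom image/mask pair
#'
#' Renders a half-elliptical breast foreground (chest wall at the left
#' image edge) with multiscale correlated texture, then inserts each
#' requested lesion as a smooth irregular blob whose realized mask area is
#' within +/-15% of its target. Lesions lie fully inside the foreground
#' and do not overlap. The returned mask marks exactly the rendered lesion
#' pixels.
#'
#' @param config a [phantom_config()].
#' @param id identifier for the pair.
#' @return an [image_pair()].
#' @export
generate_phantom <- function(config, id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config, id))
}

generate_phantom_impl <- function(config, id) {
  side <- config$image_side
  cx <- 0                       # chest wall on the left edge (column 0)
  cy <- side / 2
  a <- 0.92 * side              # ellipse semi-axes
  b <- 0.44 * side
  jj <- matrix(rep(seq_len(side), each = side), side)
  ii <- matrix(rep(seq_len(side), side), side)
  e <- sqrt(((jj - cx) / a)^2 + ((ii - cy) / b)^2)
  fg <- e <= 1
  fg_area <- sum(fg)
  if (sum(config$lesion_areas) > 0.5 * fg_area) {
    stop(sprintf(
      "infeasible configuration: total lesion area %.0f exceeds 50%% of the foreground area (%d px)",
      sum(config$lesion_areas), fg_area), call. = FALSE)
  }

  img <- matrix(0.03, side, side)
  tex <- texture_field(side, config$texture_scale)
  edge <- pmin(1, pmax(0, (1 - e) / 0.10))   # soft skin-line falloff
  tissue <- config$background_level + config$texture_amplitude * tex
  img[fg] <- (tissue * sqrt(edge))[fg]

  mask <- matrix(0L, side, side)
  n_lesions <- length(config$lesion_areas)
  contrast <- rep(config$lesion_contrast, length.out = max(n_lesions, 1))
  if (n_lesions > 0) {
    for (l in seq_len(n_lesions)) {
      area <- config$lesion_areas[l]
      rmax <- sqrt(area / pi) * 1.4 + 3
      placed <- FALSE
      for (attempt in 1:80) {
        # sample a center safely inside the foreground ellipse
        repeat {
          cj0 <- runif(1, 1, side)
          ci0 <- runif(1, 1, side)
          es <- sqrt(((cj0 - cx) / (a - rmax))^2 + ((ci0 - cy) / (b - rmax))^2)
          if (es <= 0.96 && cj0 > rmax + 1) break
        }
        blob <- render_blob(side, ci0, cj0, area)
        pix <- cbind(blob$rows, blob$cols)
        if (any(mask[pix] == 1L)) next       # overlap with earlier lesion
        if (any(e[pix] > 0.97)) next         # too close to the skin line
        mask[pix] <- 1L
        # soft-edged intensity bump; window padded so the blur tail is
        # not clipped into a visible seam
        sig <- max(1.5, sqrt(area / pi) / 4)
        pad <- ceiling(3.5 * sig)
        w <- blob$win
        w <- c(max(1, w[1] - pad), min(side, w[2] + pad),
               max(1, w[3] - pad), min(side, w[4] + pad))
        bump <- matrix(0, w[2] - w[1] + 1, w[4] - w[3] + 1)
        bump[cbind(blob$rows - w[1] + 1, blob$cols - w[3] + 1)] <- 1
        bump <- EBImage::gblur(bump, sigma = sig)
        bump <- bump / max(bump)
        img[w[1]:w[2], w[3]:w[4]] <- img[w[1]:w[2], w[3]:w[4]] +
          contrast[l] * bump
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a lesion inside the foreground; reduce lesion area",
             call. = FALSE)
      }
    }
  }
  image_pair(id, clamp01(img), mask, native_side = side)
}

categorize_area <- function(area, bounds = c(500, 1500)) {
  ifelse(area < bounds[1], "small",
         ifelse(area <= bounds[2], "medium", "large"))
}

#' Generate a cohort of single-lesion phantoms with a controlled size mix
#'
#' Produces `n_images` phantoms, one lesion per image, apportioning the
#' small/medium/large category counts by the largest-remainder rule so the
#' realized counts match `size_mix` exactly. Target areas are drawn
#' uniformly within each category's range (shrunk so the +/-15% rendering
#' tolerance cannot leave the declared interval), and the realized mask
#' area is verified against the declared interval.
#'
#' @param n_images number of images (0 yields an empty cohort).
#' @param size_mix length-3 proportions over (small, medium, large);
#'   must sum to 1.
#' @param area_ranges named list of `c(lo, hi)` pixel-area intervals for
#'   `small`, `medium`, `large`. Defaults follow the conventional
#'   small `< 500` px, medium `500-1500` px, large `> 1500` px bands.
#' @param seed integer master seed; the cohort is a pure function of its
#'   arguments.
#' @param image_side native resolution of every phantom.
#' @param contrast_by_category named numeric vector giving each category's
#'   lesion contrast, emulating the conspicuity gradient of real lesions
#'   (small lesions are fainter).
#' @param texture_scale,background_level passed to [phantom_config()].
#' @return list with `pairs` (list of [image_pair()]) and `manifest`
#'   (data.frame with columns id, area_px, category, seed).
#' @export
generate_cohort <- function(n_images,
                            size_mix = c(37, 13, 5) / 55,
                            area_ranges = list(small = c(100, 500),
                                               medium = c(500, 1500),
                                               large = c(1500, 6000)),
                            seed = 1L,
                            image_side = 1024,
                            contrast_by_category = c(small = 0.16,
                                                     medium = 0.22,
                                                     large = 0.28),
                            texture_scale = image_side / 12,
                            texture_amplitude = 0.03,
                            background_level = 0.45) {
  if (n_images == 0) {
    return(list(pairs = list(),
                manifest = data.frame(id = character(0), area_px = numeric(0),
                                      category = character(0),
                                      seed = integer(0))))
  }
  if (any(size_mix < 0)) stop("negative proportions", call. = FALSE)
  if (abs(sum(size_mix) - 1) > 1e-9) {
    stop("size_mix must sum to 1", call. = FALSE)
  }
  counts <- largest_remainder(n_images, size_mix)
  cats <- rep(c("small", "medium", "large"), counts)
  seeds <- derive_seeds(seed, n_images + 1L)
  target_draw <- with_seed(seeds[n_images + 1L], {
    vapply(cats, function(cat) {
      rg <- area_ranges[[cat]]
      runif(1, rg[1] / 0.85, rg[2] / 1.15)
    }, numeric(1))
  })
  pairs <- vector("list", n_images)
  manifest <- data.frame(id = character(n_images), area_px = numeric(n_images),
                         category = cats, seed = seeds[seq_len(n_images)],
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_images)) {
    cat_i <- cats[i]
    rg <- area_ranges[[cat_i]]
    target <- target_draw[i]
    for (attempt in 1:6) {
      cfg <- phantom_config(
        image_side = image_side, lesion_areas = target,
        lesion_contrast = unname(contrast_by_category[cat_i]),
        texture_scale = texture_scale, texture_amplitude = texture_amplitude,
        background_level = background_level,
        seed = seeds[i] + attempt - 1L)
      id <- sprintf("phantom_%03d", i)
      pair <- generate_phantom(cfg, id = id)
      if (pair$lesion_area_native >= rg[1] &&
          pair$lesion_area_native <= rg[2] &&
          identical(categorize_area(pair$lesion_area_native), cat_i)) break
      # re-center the target toward the interval midpoint and retry
      target <- (target + mean(c(rg[1] / 0.85, rg[2] / 1.15))) / 2
    }
    pairs[[i]] <- pair
    manifest$id[i] <- pair$id
    manifest$area_px[i] <- pair$lesion_area_native
  }
  list(pairs = pairs, manifest = manifest)
}

#' Write a cohort to disk as image/mask folders plus a manifest
#'
#' Images and masks are written as grayscale rasters with matching
#' basenames under `images/` and `masks/`; the manifest is a CSV with
#' columns id, area_px, category, seed. 8-bit output uses PNG; 16-bit
#' output uses TIFF (the PNG writer available here is 8-bit only).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param bit_depth 8 or 16.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, bit_depth = 8) {
  stopifnot(bit_depth %in% c(8, 16))
  if (bit_depth == 16 && !requireNamespace("tiff", quietly = TRUE)) {
    stop("16-bit output requires the 'tiff' package", call. = FALSE)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ext <- if (bit_depth == 8) ".png" else ".tiff"
  for (pair in cohort$pairs) {
    ip <- file.path(dir, "images", paste0(pair$id, ext))
    mp <- file.path(dir, "masks", paste0(pair$id, ext))
    if (bit_depth == 8) {
      png::writePNG(pair$image, ip)
      png::writePNG(pair$mask + 0, mp)
    } else {
      tiff::writeTIFF(pair$image, ip, bits.per.sample = 16)
      tiff::writeTIFF(pair$mask + 0, mp, bits.per.sample = 16)
    }
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `images/`, `masks/` and `manifest.csv`.
#' @return list with `pairs` and `manifest`, as for [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    stop(sprintf("expected manifest at %s", man_path), call. = FALSE)
  }
  manifest <- read.csv(man_path, stringsAsFactors = FALSE)
  pairs <- lapply(manifest$id, function(id) {
    ipng <- file.path(dir, "images", paste0(id, ".png"))
    itif <- file.path(dir, "images", paste0(id, ".tiff"))
    ip <- if (file.exists(ipng)) ipng else itif
    mp <- file.path(dir, "masks", basename(ip))
    read_gray <- function(p) {
      x <- if (grepl("\\.png$", p)) png::readPNG(p) else tiff::readTIFF(p)
      if (length(dim(x)) == 3) x <- x[, , 1]
      x
    }
    img <- read_gray(ip)
    msk <- binarize_mask(read_gray(mp), 0.5)
    image_pair(id, img, msk, native_side = nrow(img))
  })
  list(pairs = pairs, manifest = manifest)
}
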