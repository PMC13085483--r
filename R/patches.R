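#' Patch sampler configuration
#'
#' Defaults encode the Stage-1 sampling protocol: 224 x 224 lesion-centered
#' positive patches, negatives at a 2:1 negative-to-positive ratio with
#' mask coverage below 5%, an 80/20 train/validation split (by source
#' image), and a 35% hybrid substitution probability for Stage-2 batches.
#'
#' @param patch_side patch side in pixels.
#' @param neg_per_pos negative patches sampled per positive patch.
#' @param neg_max_coverage maximal lesion-mask coverage fraction of a
#'   negative patch (strict upper bound).
#' @param centroid_jitter_frac centroid jitter amplitude as a fraction of
#'   the patch side (uniform in +/- jitter per axis).
#' @param positives_per_lesion number of jittered positive patches
#'   extracted per lesion-bearing image.
#' @param split_train_frac training fraction of the patch-source images.
#' @param hybrid_substitution_prob probability that a Stage-2 training
#'   sample is replaced by a lesion patch.
#' @param foreground_min_frac when positive, candidate negative windows
#'   must contain at least this fraction of breast-foreground pixels
#'   (estimated by intensity thresholding); set to 0 to disable.
#' @param attempt_budget rejection-sampling attempts per negative patch.
#' @param seed integer seed used by dataset-level operations.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(patch_side = 224L, neg_per_pos = 2L,
                           neg_max_coverage = 0.05,
                           centroid_jitter_frac = 0.25,
                           positives_per_lesion = 1L,
                           split_train_frac = 0.8,
                           hybrid_substitution_prob = 0.35,
                           foreground_min_frac = 0.5,
                           attempt_budget = 100L, seed = 1L) {
  stopifnot(patch_side >= 16, neg_per_pos >= 0,
            neg_max_coverage > 0, neg_max_coverage < 1,
            split_train_frac > 0, split_train_frac < 1,
            hybrid_substitution_prob >= 0, hybrid_substitution_prob <= 1)
  structure(as.list(environment()), class = "sampler_config")
}

#' Bounding box and centroid of a binary mask
#'
#' @param mask binary matrix.
#' @return `NULL` when the mask is empty (the explicit "no lesion"
#'   result); otherwise a list with `rmin`, `rmax`, `cmin`, `cmax` and
#'   `centroid` (mean row/col of positive pixels).
#' @export
lesion_bbox <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  list(rmin = min(w[, 1]), rmax = max(w[, 1]),
       cmin = min(w[, 2]), cmax = max(w[, 2]),
       centroid = c(mean(w[, 1]), mean(w[, 2])))
}

patch_sample <- function(image_crop, mask_crop, label, source_id, origin,
                         coverage = mean(mask_crop)) {
  structure(list(image_crop = image_crop, mask_crop = mask_crop,
                 label = label, source_id = source_id, origin = origin,
                 coverage = coverage), class = "patch_sample")
}

# Clamp a window's top-left corner so a patch of side `ps` fits in `side`.
clamp_origin <- function(x, ps, side) max(1L, min(as.integer(x), side - ps + 1L))

crop_window <- function(mat, r0, c0, ps) {
  mat[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
}

#' Extract one lesion-centered positive patch
#'
#' The patch is centered on the lesion centroid plus a uniform jitter of
#' up to `centroid_jitter_frac * patch_side` per axis, clamped so the
#' window lies inside the image. The returned mask crop is always
#' non-empty.
#'
#' @param pair an [image_pair()] with a non-empty mask.
#' @param config a [sampler_config()].
#' @return a `patch_sample` with label `"positive"`.
#' @export
extract_positive_patch <- function(pair, config = sampler_config()) {
  ps <- config$patch_side
  side <- nrow(pair$image)
  if (side < ps || ncol(pair$image) < ps) {
    stop(sprintf("image side %d x %d smaller than patch side %d",
                 nrow(pair$image), ncol(pair$image), ps), call. = FALSE)
  }
  bb <- lesion_bbox(pair$mask)
  if (is.null(bb)) stop("pair has an empty mask", call. = FALSE)
  jit <- config$centroid_jitter_frac * ps
  for (attempt in 1:20) {
    ctr <- bb$centroid + runif(2, -jit, jit)
    r0 <- clamp_origin(round(ctr[1] - ps / 2), ps, side)
    c0 <- clamp_origin(round(ctr[2] - ps / 2), ps, ncol(pair$image))
    mc <- crop_window(pair$mask, r0, c0, ps)
    if (sum(mc) > 0) break
    jit <- jit / 2   # lesion escaped the window: shrink the jitter
  }
  patch_sample(crop_window(pair$image, r0, c0, ps), mc, "positive",
               pair$id, c(r0, c0))
}

# Foreground estimate for negative-window screening: pixels meaningfully
# brighter than the darkest background.
estimate_foreground <- function(image) {
  rng <- range(image)
  image > rng[1] + 0.15 * diff(rng)
}

#' Sample background (negative) patches
#'
#' Draws up to `n` windows uniformly over the image, accepting a window
#' only if its lesion-mask coverage is strictly below
#' `neg_max_coverage` (and, when `foreground_min_frac > 0`, if at least
#' that fraction of the window lies on the breast foreground). Rejection
#' sampling stops after `attempt_budget` attempts per patch; if the
#' budget is exhausted fewer patches are returned with a warning, never a
#' mislabeled one.
#'
#' @param pair an [image_pair()].
#' @param config a [sampler_config()].
#' @param n number of negatives requested (default `neg_per_pos`).
#' @return list of `patch_sample` objects with label `"negative"`.
#' @export
sample_negative_patches <- function(pair, config = sampler_config(),
                                    n = config$neg_per_pos) {
  ps <- config$patch_side
  h <- nrow(pair$image); w <- ncol(pair$image)
  if (h < ps || w < ps) {
    stop(sprintf("image side %d x %d smaller than patch side %d", h, w, ps),
         call. = FALSE)
  }
  fg <- if (config$foreground_min_frac > 0) estimate_foreground(pair$image)
        else NULL
  out <- list()
  for (k in seq_len(n)) {
    got <- FALSE
    for (attempt in seq_len(config$attempt_budget)) {
      r0 <- sample.int(h - ps + 1L, 1L)
      c0 <- sample.int(w - ps + 1L, 1L)
      mc <- crop_window(pair$mask, r0, c0, ps)
      cov <- mean(mc)
      if (cov >= config$neg_max_coverage) next
      if (!is.null(fg) &&
          mean(crop_window(fg, r0, c0, ps)) < config$foreground_min_frac) next
      out[[length(out) + 1L]] <- patch_sample(
        crop_window(pair$image, r0, c0, ps), mc, "negative", pair$id,
        c(r0, c0), coverage = cov)
      got <- TRUE
      break
    }
    if (!got) {
      warning(sprintf("negative-patch attempt budget exhausted for '%s': %d of %d sampled",
                      pair$id, length(out), n))
      break
    }
  }
  out
}

#' Build the Stage-1 patch dataset with an 80/20 split by source image
#'
#' Extracts `positives_per_lesion` positive patches and
#' `neg_per_pos`-per-positive negative patches from every pair, then
#' splits by source image (all patches of one image land in one split) to
#' prevent leakage. Patches carry a stochastic horizontal/vertical flip
#' augmentation flag honored by the training loop.
#'
#' @param pairs list of at least two [image_pair()] objects.
#' @param config a [sampler_config()]; `config$seed` drives the split and
#'   all sampling.
#' @return list with `train` and `validation` patch lists, and
#'   `train_ids` / `validation_ids` of source images.
#' @export
build_patch_dataset <- function(pairs, config = sampler_config()) {
  if (length(pairs) < 2) stop("need at least 2 source images", call. = FALSE)
  with_seed(config$seed, {
    ids <- vapply(pairs, function(p) p$id, character(1))
    ord <- sample(seq_along(pairs))
    n_train <- max(1L, min(length(pairs) - 1L,
                           round(config$split_train_frac * length(pairs))))
    train_idx <- ord[seq_len(n_train)]
    extract_all <- function(idx) {
      out <- list()
      for (i in idx) {
        pair <- pairs[[i]]
        if (sum(pair$mask) > 0) {
          for (k in seq_len(config$positives_per_lesion)) {
            out[[length(out) + 1L]] <- extract_positive_patch(pair, config)
            negs <- sample_negative_patches(pair, config)
            out <- c(out, negs)
          }
        }
      }
      out
    }
    list(train = extract_all(sort(train_idx)),
         validation = extract_all(sort(setdiff(seq_along(pairs), train_idx))),
         train_ids = sort(ids[train_idx]),
         validation_ids = sort(ids[setdiff(seq_along(pairs), train_idx)]))
  })
}

#' Hybrid full-image/patch sample stream for Stage-2 fine-tuning
#'
#' Returns a sampler closure. Each draw is, independently with probability
#' `hybrid_substitution_prob`, a positive lesion patch from `patch_pool`
#' (enforcing lesion presence in a subset of samples), otherwise a full
#' image drawn from `full_pairs`. Both sources must already match the
#' model input resolution.
#'
#' @param full_pairs non-empty list of model-resolution [image_pair()]s.
#' @param patch_pool list of `patch_sample` objects; positive patches are
#'   required when the substitution probability is positive.
#' @param config a [sampler_config()].
#' @return function `draw(n)` returning a list of samples, each a list
#'   with `image`, `mask` and `source` (`"full"` or `"patch"`).
#' @export
hybrid_sampler <- function(full_pairs, patch_pool, config = sampler_config()) {
  if (length(full_pairs) == 0) stop("empty full_pairs", call. = FALSE)
  pos_pool <- Filter(function(p) identical(p$label, "positive"), patch_pool)
  if (config$hybrid_substitution_prob > 0 && length(pos_pool) == 0) {
    stop("hybrid substitution requested but patch pool has no positive patches",
         call. = FALSE)
  }
  function(n) {
    lapply(seq_len(n), function(k) {
      if (runif(1) < config$hybrid_substitution_prob) {
        p <- pos_pool[[sample.int(length(pos_pool), 1L)]]
        list(image = p$image_crop, mask = p$mask_crop, source = "patch")
      } else {
        fp <- full_pairs[[sample.int(length(full_pairs), 1L)]]
        list(image = fp$image, mask = fp$mask, source = "full")
      }
    })
  }
}

#' Write a patch dataset as PNG folders plus a CSV index
#'
#' @param dataset result of [build_patch_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_patch_dataset <- function(dataset, dir) {
  idx <- data.frame(patch_id = character(0), source_id = character(0),
                    split = character(0), label = character(0),
                    origin_row = integer(0), origin_col = integer(0),
                    coverage = numeric(0))
  for (split in c("train", "validation")) {
    sub <- file.path(dir, split)
    dir.create(file.path(sub, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(sub, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(dataset[[split]])) {
      p <- dataset[[split]][[k]]
      pid <- sprintf("%s_%s_%03d", p$source_id, substr(p$label, 1, 3), k)
      png::writePNG(p$image_crop, file.path(sub, "images", paste0(pid, ".png")))
      png::writePNG(p$mask_crop + 0, file.path(sub, "masks", paste0(pid, ".png")))
      idx <- rbind(idx, data.frame(patch_id = pid, source_id = p$source_id,
                                   split = split, label = p$label,
                                   origin_row = p$origin[1],
                                   origin_col = p$origin[2],
                                   coverage = p$coverage))
    }
  }
  write.csv(idx, file.path(dir, "patch_index.csv"), row.names = FALSE)
  invisible(dir)
}
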