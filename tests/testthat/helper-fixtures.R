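# Shared fixtures, generated in code at test time.

# A small phantom pair with one lesion, cached across tests.
tiny_pair <- local({
  cache <- NULL
  function(side = 256, area = 600, seed = 11) {
    if (is.null(cache)) {
      cfg <- phantom_config(image_side = side, lesion_areas = area,
                            lesion_contrast = 0.3, seed = seed)
      cache <<- generate_phantom(cfg, id = "tiny")
    }
    cache
  }
})

# A miniature network configuration for fast training tests.
mini_unet_config <- function(input_side = 64L) {
  unet_config(input_side = input_side, encoder_filters = c(4L, 8L),
              bottleneck_filters = 12L, dropout_rate = 0.3)
}

# Random binary mask matrices for metric oracle tests.
random_mask <- function(side, p) {
  matrix(as.integer(runif(side * side) < p), side, side)
}

# Brute-force confusion-count metrics (independent oracle).
oracle_counts <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1) fp <- fp + 1
      else if (gt[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force all-pairs symmetric Hausdorff distance.
oracle_hausdorff <- function(pred, gt) {
  A <- which(pred == 1, arr.ind = TRUE)
  B <- which(gt == 1, arr.ind = TRUE)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (a in seq_len(nrow(A))) {
    for (b in seq_len(nrow(B))) {
      dmat[a, b] <- sqrt(sum((A[a, ] - B[b, ])^2))
    }
  }
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
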