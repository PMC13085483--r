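test_that("lesion_bbox reports tight boxes, centroids and the empty case", {
  m <- matrix(0L, 30, 30); m[10, 20] <- 1L
  bb <- lesion_bbox(m)
  expect_equal(c(bb$rmin, bb$rmax, bb$cmin, bb$cmax), c(10, 10, 20, 20))
  expect_equal(bb$centroid, c(10, 20))

  m2 <- matrix(0L, 30, 30); m2[4:6, 7:9] <- 1L
  expect_equal(lesion_bbox(m2)$centroid, c(5, 8))

  expect_null(lesion_bbox(matrix(0L, 5, 5)))
})

test_that("positive patches are lesion-centered with clamped jitter", {
  pair <- tiny_pair()
  cfg <- sampler_config(patch_side = 96L, centroid_jitter_frac = 0)
  set.seed(1)
  p <- extract_positive_patch(pair, cfg)
  bb <- lesion_bbox(pair$mask)
  expect_equal(p$origin[1], round(bb$centroid[1] - 48))
  expect_identical(dim(p$image_crop), c(96L, 96L))
  expect_identical(p$label, "positive")

  # with jitter on, every draw still contains lesion pixels
  cfgj <- sampler_config(patch_side = 96L, centroid_jitter_frac = 0.25)
  set.seed(2)
  ok <- vapply(1:300, function(i) {
    sum(extract_positive_patch(pair, cfgj)$mask_crop) > 0
  }, logical(1))
  expect_true(all(ok))

  # lesion near a corner: window is clamped inside the image
  mc <- matrix(0L, 256, 256); mc[1:6, 1:6] <- 1L
  corner <- image_pair("c", matrix(0.5, 256, 256), mc)
  set.seed(3)
  pc <- extract_positive_patch(corner, cfgj)
  expect_gte(pc$origin[1], 1)
  expect_gte(pc$origin[2], 1)
  expect_gt(sum(pc$mask_crop), 0)

  small <- image_pair("s", matrix(0.5, 64, 64),
                      {m <- matrix(0L, 64, 64); m[30, 30] <- 1L; m})
  expect_error(extract_positive_patch(small, sampler_config(patch_side = 96L)),
               "smaller than patch side")
})

test_that("negative patches always satisfy the coverage bound", {
  pair <- tiny_pair()
  cfg <- sampler_config(patch_side = 96L, neg_per_pos = 2L,
                        foreground_min_frac = 0)
  set.seed(4)
  negs <- sample_negative_patches(pair, cfg, n = 20)
  expect_length(negs, 20)
  for (ng in negs) {
    expect_lt(mean(ng$mask_crop), 0.05)
    expect_identical(ng$label, "negative")
  }

  # an all-zero mask qualifies any window
  blank <- image_pair("b", matrix(0.5, 128, 128), matrix(0L, 128, 128))
  set.seed(5)
  nb <- sample_negative_patches(blank, sampler_config(patch_side = 64L,
                                                      foreground_min_frac = 0))
  expect_length(nb, 2)
  expect_true(all(vapply(nb, function(p) p$coverage, numeric(1)) == 0))

  # lesion covering nearly the whole image exhausts the budget gracefully
  big <- matrix(1L, 128, 128); big[1, 1] <- 0L
  hard <- image_pair("h", matrix(0.5, 128, 128), big)
  set.seed(6)
  expect_warning(
    nh <- sample_negative_patches(hard, sampler_config(patch_side = 64L,
                                                       attempt_budget = 20L,
                                                       foreground_min_frac = 0)),
    "budget")
  expect_length(nh, 0)
})

test_that("patch datasets split by source image without leakage", {
  set.seed(7)
  pairs <- lapply(1:10, function(i) {
    cfg <- phantom_config(image_side = 256, lesion_areas = 500,
                          lesion_contrast = 0.3, seed = 100 + i)
    generate_phantom(cfg, id = sprintf("img%02d", i))
  })
  cfg <- sampler_config(patch_side = 128L, seed = 31)
  ds <- build_patch_dataset(pairs, cfg)
  expect_length(ds$train_ids, 8)
  expect_length(ds$validation_ids, 2)
  expect_length(intersect(ds$train_ids, ds$validation_ids), 0)
  # per image: 1 positive + 2 negatives when feasible
  expect_equal(length(ds$train) + length(ds$validation), 3 * 10)
  for (p in c(ds$train, ds$validation)) {
    if (p$label == "negative") expect_lt(p$coverage, 0.05)
    if (p$label == "positive") expect_gt(sum(p$mask_crop), 0)
  }
  # reproducibility
  ds2 <- build_patch_dataset(pairs, cfg)
  expect_identical(ds$train_ids, ds2$train_ids)
  expect_identical(ds$train[[1]]$image_crop, ds2$train[[1]]$image_crop)

  expect_error(build_patch_dataset(pairs[1], cfg), "at least 2")
})

test_that("the 80/20 image split matches round(0.8 n) for printed cohorts", {
  ids <- sprintf("im%03d", 1:159)
  pairs <- lapply(ids, function(id) {
    image_pair(id, matrix(0.5, 32, 32), matrix(0L, 32, 32))
  })
  cfg <- sampler_config(patch_side = 16L, seed = 2)
  ds <- build_patch_dataset(pairs, cfg)
  expect_length(ds$train_ids, 127)   # round(0.8 * 159)
  expect_length(ds$validation_ids, 32)
})

test_that("hybrid sampling substitutes patches at the configured rate", {
  pair <- tiny_pair()
  cfg <- sampler_config(patch_side = 96L)
  set.seed(8)
  pos <- extract_positive_patch(pair, cfg)
  full <- list(image_pair("f", matrix(0.4, 96, 96), matrix(0L, 96, 96)))

  s0 <- hybrid_sampler(full, list(pos), sampler_config(hybrid_substitution_prob = 0))
  set.seed(9)
  expect_true(all(vapply(s0(50), `[[`, character(1), "source") == "full"))

  s1 <- hybrid_sampler(full, list(pos), sampler_config(hybrid_substitution_prob = 1))
  expect_true(all(vapply(s1(50), `[[`, character(1), "source") == "patch"))

  expect_error(hybrid_sampler(full, list(), sampler_config()), "positive")

  # substituted fraction over 10,000 draws lies in the 99% binomial band
  s35 <- hybrid_sampler(full, list(pos),
                        sampler_config(hybrid_substitution_prob = 0.35))
  set.seed(123)
  frac <- mean(vapply(s35(10000), `[[`, character(1), "source") == "patch")
  expect_gte(frac, 0.3366)
  expect_lte(frac, 0.3634)
})
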