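test_that("lesion-free phantom has an all-zero mask", {
  cfg <- phantom_config(image_side = 256, lesion_areas = numeric(0), seed = 4)
  p <- generate_phantom(cfg)
  expect_equal(sum(p$mask), 0)
  expect_equal(p$lesion_area_native, 0)
  expect_true(all(p$image >= 0 & p$image <= 1))
  expect_identical(dim(p$image), dim(p$mask))
})

test_that("phantom generation is a pure function of its config", {
  cfg <- phantom_config(image_side = 256, lesion_areas = c(300, 500),
                        seed = 21)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_phantom(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("realized lesion area is within 15% of the target", {
  for (seed in c(2, 7, 13)) {
    cfg <- phantom_config(image_side = 256, lesion_areas = 400, seed = seed)
    p <- generate_phantom(cfg)
    expect_gte(p$lesion_area_native, 340)
    expect_lte(p$lesion_area_native, 460)
  }
})

test_that("lesions lie inside the breast foreground and match the mask", {
  cfg <- phantom_config(image_side = 256, lesion_areas = c(400, 900),
                        lesion_contrast = 0.3, seed = 5)
  p <- generate_phantom(cfg)
  expect_setequal(unique(as.vector(p$mask)), c(0L, 1L))
  expect_equal(p$lesion_area_native, sum(p$mask))
  # every mask pixel sits on tissue brighter than the dark background
  expect_true(all(p$image[p$mask == 1] > 0.2))
})

test_that("infeasible total lesion area raises a configuration error", {
  cfg <- phantom_config(image_side = 256, lesion_areas = 256^2 * 0.4,
                        seed = 1)
  expect_error(generate_phantom(cfg), "infeasible")
})

test_that("cohort apportionment follows the largest-remainder rule", {
  co <- generate_cohort(0, seed = 1)
  expect_equal(nrow(co$manifest), 0)
  expect_length(co$pairs, 0)

  expect_error(generate_cohort(5, size_mix = c(-0.2, 0.6, 0.6)), "negative")

  # hand-derived largest-remainder apportionments
  expect_identical(mammoseg:::largest_remainder(20, c(0.5, 0.3, 0.2)),
                   c(10L, 6L, 4L))
  expect_identical(mammoseg:::largest_remainder(55, c(37, 13, 5) / 55),
                   c(37L, 13L, 5L))
  expect_identical(mammoseg:::largest_remainder(3, c(1, 0, 0)),
                   c(3L, 0L, 0L))
})

test_that("cohort manifest areas lie inside their declared category bands", {
  co <- generate_cohort(8, size_mix = c(0.5, 0.25, 0.25), seed = 42,
                        image_side = 320)
  expect_equal(table(factor(co$manifest$category,
                            c("small", "medium", "large")))[["small"]], 4)
  ranges <- list(small = c(100, 500), medium = c(500, 1500),
                 large = c(1500, 6000))
  for (i in seq_len(nrow(co$manifest))) {
    rg <- ranges[[co$manifest$category[i]]]
    expect_gte(co$manifest$area_px[i], rg[1])
    expect_lte(co$manifest$area_px[i], rg[2])
    expect_equal(co$manifest$area_px[i], co$pairs[[i]]$lesion_area_native)
  }
  # determinism of the whole cohort
  co2 <- generate_cohort(8, size_mix = c(0.5, 0.25, 0.25), seed = 42,
                         image_side = 320)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$pairs[[3]]$image, co2$pairs[[3]]$image)
})

test_that("cohorts round-trip through the on-disk folder layout", {
  co <- generate_cohort(3, size_mix = c(1, 0, 0), seed = 9, image_side = 256)
  expect_identical(unique(co$manifest$category), "small")
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "images", "phantom_001.png")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$area_px, co$manifest$area_px)
  # 8-bit quantization: images agree to 1/255, masks exactly
  expect_lt(max(abs(back$pairs[[1]]$image - co$pairs[[1]]$image)), 1 / 254)
  expect_identical(back$pairs[[1]]$mask == 1, co$pairs[[1]]$mask == 1)
})
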