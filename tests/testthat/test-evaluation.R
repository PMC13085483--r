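test_that("detection uses a strict IoU threshold", {
  expect_false(detect_lesion(0.10))
  expect_true(detect_lesion(0.11))
  expect_false(detect_lesion(0))
  expect_identical(detect_lesion(c(0.05, 0.10, 0.2)), c(FALSE, FALSE, TRUE))
})

test_that("size categories assign their boundary values to medium", {
  expect_identical(mammoseg:::categorize_area(c(499, 500, 1500, 1501)),
                   c("small", "medium", "medium", "large"))
})

test_that("stratification reproduces count-table detection rates", {
  # 37 small (27 detected), 13 medium (11), 5 large (5)
  iou <- c(rep(0.5, 27), rep(0.05, 10),
           rep(0.5, 11), rep(0.05, 2),
           rep(0.5, 5))
  area <- c(rep(200, 37), rep(800, 13), rep(2000, 5))
  rec <- eval_records(id = sprintf("r%02d", 1:55), iou = iou, dice = iou,
                      lesion_area = area)
  rep <- stratify_records(rec)
  expect_equal(rep$per_category$n, c(37, 13, 5))
  expect_equal(rep$per_category$n_detected, c(27, 11, 5))
  expect_equal(round(rep$per_category$detection_rate_pct, 1),
               c(73.0, 84.6, 100.0))
  expect_equal(round(rep$overall_detection_rate_pct, 1), 78.2)
  expect_equal(round(rep$missed_share_pct, 1), 21.8)
  # partition: every record in exactly one category
  expect_equal(sum(rep$per_category$n), rep$n_total)
  # aggregate consistency
  expect_equal(rep$n_detected, sum(rec$detected))
})

test_that("raising the detection threshold never raises a detection rate", {
  set.seed(3)
  rec_at <- function(thr) {
    eval_records(id = sprintf("x%02d", 1:40), iou = runif(40, 0, 0.4),
                 dice = runif(40), lesion_area = runif(40, 100, 3000),
                 detection_threshold = thr)
  }
  set.seed(3); r1 <- stratify_records(rec_at(0.10))
  set.seed(3); r2 <- stratify_records(rec_at(0.25))
  ok <- !is.na(r1$per_category$detection_rate_pct)
  expect_true(all(r2$per_category$detection_rate_pct[ok] <=
                  r1$per_category$detection_rate_pct[ok]))
})

test_that("kruskal-wallis matches the hand-computed example and oracle", {
  kw <- kruskal_wallis_test(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  expect_equal(kruskal_wallis_test(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)

  degenerate <- kruskal_wallis_test(list(c(2, 2), c(2, 2, 2)))
  expect_equal(degenerate$H, 0)
  expect_equal(degenerate$p, 1)

  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(3:10, 1)), sample(0:2, 1))  # induce ties
    })
    ours <- kruskal_wallis_test(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(seq_len(k), lengths(groups))))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("mann-whitney matches the reference normal approximation", {
  set.seed(12)
  for (i in 1:100) {
    x <- round(rnorm(sample(4:12, 1)), 1)
    y <- round(rnorm(sample(4:12, 1), mean = runif(1, -1, 1)), 1)
    ours <- mann_whitney_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$W, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("missed-vs-detected compares group means with a rank test", {
  rec <- eval_records(id = sprintf("m%d", 1:4), iou = c(0.05, 0.05, 0.5, 0.5),
                      dice = c(0, 0, 0.6, 0.7),
                      lesion_area = c(100, 300, 900, 1300))
  cmp <- compare_missed_vs_detected(rec)
  expect_equal(cmp$mean_missed, 200)
  expect_equal(cmp$mean_detected, 1100)

  set.seed(4)
  rec2 <- eval_records(id = sprintf("n%d", 1:20),
                       iou = rep(c(0.05, 0.5), each = 10),
                       dice = runif(20),
                       lesion_area = c(1:10, 101:110))
  expect_lt(compare_missed_vs_detected(rec2)$p_rank, 0.001)

  all_det <- eval_records(id = "a", iou = 0.5, dice = 0.5, lesion_area = 100)
  cmp3 <- compare_missed_vs_detected(all_det)
  expect_true(is.na(cmp3$p_rank))
  expect_true(is.na(cmp3$mean_missed))
})

test_that("size-quality correlations cover linear, null and constant cases", {
  rec <- eval_records(id = c("a", "b", "c"), iou = c(0.2, 0.3, 0.4),
                      dice = c(0.2, 0.4, 0.6), lesion_area = c(600, 1200, 1800))
  expect_equal(size_quality_correlation(rec, "dice"), 1.0)

  set.seed(5)
  recn <- eval_records(id = sprintf("n%03d", 1:500),
                       iou = runif(500, 0.2, 0.9),
                       dice = runif(500, 0.2, 0.9),
                       lesion_area = runif(500, 100, 5000))
  expect_lt(abs(size_quality_correlation(recn, "dice")), 0.15)

  const <- eval_records(id = c("a", "b", "c"), iou = rep(0.5, 3),
                        dice = rep(0.5, 3), lesion_area = c(1, 2, 3))
  expect_true(is.na(size_quality_correlation(const, "dice")))
})

test_that("resolution analysis reproduces the downsampling arithmetic", {
  r1 <- resolution_analysis(4000, 224, 250)
  expect_equal(r1$fold_reduction, 4000 / 224, tolerance = 1e-12)
  expect_equal(round(r1$fold_reduction, 2), 17.86)
  expect_equal(round(r1$equivalent_area, 1), 0.8)

  r2 <- resolution_analysis(6000, 224, 250)
  expect_equal(round(r2$fold_reduction, 2), 26.79)
  expect_equal(round(r2$equivalent_area, 1), 0.3)

  r3 <- resolution_analysis(224, 224, 123)
  expect_equal(r3$fold_reduction, 1)
  expect_equal(r3$equivalent_area, 123)
})

test_that("evaluate_test_set handles perfect and empty predictors", {
  pair <- tiny_pair()
  rp <- resize_pair(pair, 64)

  # ground truth as its own prediction, and the all-zero predictor
  gm <- binarize_mask(rp$mask + 0, 0.5)
  mb_perfect <- metric_bundle(gm, gm)
  expect_equal(mb_perfect$dice, 1)
  expect_equal(mb_perfect$hausdorff, 0)

  empty <- matrix(0L, 64, 64)
  mb_empty <- metric_bundle(empty, gm)
  expect_equal(mb_empty$dice, 0)
  expect_true(is.na(mb_empty$hausdorff))

  # end-to-end with an untrained network: records are well-formed and
  # deterministic
  m <- build_unet(mini_unet_config(64L), seed = 2)
  rec1 <- evaluate_test_set(m, list(rp, rp), area_basis = "model")
  rec2 <- evaluate_test_set(m, list(rp, rp), area_basis = "model")
  expect_identical(rec1$dice, rec2$dice)
  expect_true(all(rec1$size_category %in% c("small", "medium", "large")))
  expect_error(evaluate_test_set(m, list()), "empty")
})
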