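test_that("split_dataset honors explicit counts and fractions", {
  items <- as.list(1:269)
  sp <- split_dataset(items, spec = c(159, 55, 55), seed = 1)
  expect_length(sp$train, 159)
  expect_length(sp$validation, 55)
  expect_length(sp$test, 55)
  all_idx <- c(sp$train_idx, sp$validation_idx, sp$test_idx)
  expect_setequal(all_idx, 1:269)          # disjoint and exhaustive
  expect_length(all_idx, 269)

  sp10 <- split_dataset(as.list(1:10), spec = c(0.6, 0.2, 0.2), seed = 2)
  expect_length(sp10$train, 6)
  expect_length(sp10$validation, 2)
  expect_length(sp10$test, 2)

  sp_a <- split_dataset(items, spec = c(159, 55, 55), seed = 7)
  sp_b <- split_dataset(items, spec = c(159, 55, 55), seed = 7)
  expect_identical(sp_a$train_idx, sp_b$train_idx)

  expect_error(split_dataset(as.list(1:10), spec = c(5, 3, 3), seed = 1),
               "sum to")
})

make_patchset <- function(n = 6, side = 32, seed = 10) {
  with_seed <- mammoseg:::with_seed
  with_seed(seed, lapply(seq_len(n), function(i) {
    img <- matrix(runif(side^2, 0, 0.3), side, side)
    msk <- matrix(0L, side, side)
    if (i %% 3 != 0) {       # two of three patches carry a lesion
      r <- sample(5:(side - 10), 1)
      msk[r:(r + 5), r:(r + 5)] <- 1L
      img[msk == 1] <- img[msk == 1] + 0.6
    }
    structure(list(image_crop = img, mask_crop = msk,
                   label = if (sum(msk) > 0) "positive" else "negative",
                   source_id = sprintf("p%d", i), origin = c(1L, 1L),
                   coverage = mean(msk)), class = "patch_sample")
  }))
}

test_that("pretraining tracks history, checkpoints and early stopping", {
  ps <- make_patchset(8)
  model <- build_unet(mini_unet_config(32L), seed = 1)
  cfg <- train_config(max_epochs = 2L, batch_size = 4L, seed = 3)
  res <- pretrain_on_patches(model, ps[1:6], ps[7:8], loss_config(), cfg)
  expect_equal(nrow(res$history), 2)
  expect_true(all(c("train_loss", "val_dice") %in% names(res$history)))
  expect_equal(attr(res$history, "checkpoint_epoch"),
               which.max(res$history$val_dice))

  # a frozen model (lr ~ 0) with a structurally flat monitored metric
  # (all-background validation, whose Dice cannot drift): patience 1
  # stops at epoch 2
  flat_val <- lapply(ps[7:8], function(p) {
    p$mask_crop <- matrix(0L, nrow(p$mask_crop), ncol(p$mask_crop))
    p
  })
  cfg_flat <- train_config(learning_rate = 1e-30, max_epochs = 10L,
                           batch_size = 4L, early_stop_patience = 1L,
                           seed = 3)
  res_flat <- pretrain_on_patches(model, ps[1:6], flat_val, loss_config(),
                                  cfg_flat)
  expect_equal(nrow(res_flat$history), 2)
  expect_identical(attr(res_flat$history, "stop_reason"), "early_stopping")

  expect_error(pretrain_on_patches(model, list(), ps[7:8], loss_config(),
                                   cfg), "empty")
})

test_that("learning rate decays on plateau and never increases", {
  ps <- make_patchset(8)
  model <- build_unet(mini_unet_config(32L), seed = 1)
  cfg <- train_config(learning_rate = 1e-30, max_epochs = 6L,
                      batch_size = 4L, early_stop_patience = 10L,
                      lr_decay_factor = 0.5, lr_decay_patience = 2L,
                      seed = 3)
  res <- pretrain_on_patches(model, ps[1:6], ps[7:8], loss_config(), cfg)
  expect_true(all(diff(res$history$lr) <= 0))
  expect_lt(res$history$lr[6], res$history$lr[1])
})

test_that("a short pretraining run improves the training Dice", {
  ps <- make_patchset(12, seed = 21)
  model <- build_unet(mini_unet_config(32L), seed = 2)
  cfg <- train_config(learning_rate = 2e-3, max_epochs = 12L,
                      batch_size = 4L, early_stop_patience = 20L, seed = 5)
  res <- pretrain_on_patches(model, ps[1:9], ps[10:12], loss_config(), cfg)
  expect_gt(tail(res$history$train_dice, 1), res$history$train_dice[1])
})

test_that("fine-tuning transfers the encoder and keeps the checkpoint", {
  ps <- make_patchset(6, seed = 31)
  model <- build_unet(mini_unet_config(32L), seed = 4)
  cfg1 <- train_config(max_epochs = 2L, batch_size = 4L, seed = 6)
  s1 <- pretrain_on_patches(model, ps[1:4], ps[5:6], loss_config(), cfg1)

  full <- lapply(1:6, function(i) {
    m <- matrix(0L, 32, 32); m[10:14, 10:14] <- 1L
    img <- matrix(runif(1024, 0, 0.3), 32, 32); img[m == 1] <- 0.9
    image_pair(sprintf("f%d", i), img, m)
  })
  scfg <- sampler_config(patch_side = 32L, hybrid_substitution_prob = 0.35,
                         seed = 1)
  cfg2 <- train_config(max_epochs = 2L, batch_size = 4L, seed = 7)
  s2 <- finetune_full_images(s1$model, full[1:4], full[5:6],
                             ps[1:4], loss_config(), cfg2, scfg)
  expect_equal(nrow(s2$history), 2)
  # checkpoint reproduces its recorded validation Dice
  val <- mammoseg:::validate_model(s2$model,
                                   lapply(full[5:6], function(p) {
                                     list(image = p$image, mask = p$mask + 0)
                                   }), loss_config())
  expect_equal(val$dice, attr(s2$history, "best_val_dice"), tolerance = 1e-6)

  # substitution probability zero keeps full-image provenance only
  sampler <- hybrid_sampler(full, ps[1:4],
                            sampler_config(patch_side = 32L,
                                           hybrid_substitution_prob = 0))
  set.seed(1)
  expect_true(all(vapply(sampler(20), `[[`, character(1),
                         "source") == "full"))
})

test_that("training runs are deterministic given seed, config and data", {
  ps <- make_patchset(6, seed = 41)
  model <- build_unet(mini_unet_config(32L), seed = 4)
  cfg <- train_config(max_epochs = 2L, batch_size = 4L, seed = 11)
  r1 <- pretrain_on_patches(model, ps[1:4], ps[5:6], loss_config(), cfg)
  r2 <- pretrain_on_patches(model, ps[1:4], ps[5:6], loss_config(), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})
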