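test_that("configuration invariants are enforced at build time", {
  expect_error(unet_config(encoder_filters = c(64L, 64L, 128L)),
               "strictly increasing")
  expect_error(unet_config(input_side = 100L), "divisible")
})

test_that("a scaled-down network preserves shape and emits probabilities", {
  m <- build_unet(mini_unet_config(64L), seed = 5)
  x <- matrix(runif(64 * 64), 64, 64)
  fw <- unet_forward(m, list(x))
  expect_identical(dim(fw$probs[[1]]), c(64L, 64L))
  expect_true(all(fw$probs[[1]] > 0 & fw$probs[[1]] < 1))
})

test_that("the default architecture matches its stated widths", {
  cfg <- unet_config()
  expect_identical(cfg$encoder_filters, c(64L, 128L, 256L))
  expect_identical(cfg$bottleneck_filters, 512L)
  expect_equal(cfg$dropout_rate, 0.3)
  m <- build_unet(cfg, seed = 1)
  # regression guard: parameter count of the default configuration
  expect_equal(m$n_params, 7701825)
  expect_true(all(grepl("^(enc|bott|dec|head)", m$manifest$layer)))
})

test_that("builds are deterministic given config and seed", {
  cfg <- mini_unet_config(64L)
  a <- build_unet(cfg, seed = 9)
  b <- build_unet(cfg, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$params, b$params)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(unet_forward(a, list(x))$probs,
                   unet_forward(b, list(x))$probs)
})

test_that("dropout perturbs training mode but not inference", {
  m <- build_unet(mini_unet_config(64L), seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  set.seed(1); t1 <- unet_forward(m, list(x), training = TRUE)$probs[[1]]
  set.seed(2); t2 <- unet_forward(m, list(x), training = TRUE)$probs[[1]]
  expect_false(identical(t1, t2))
  i1 <- unet_forward(m, list(x))$probs[[1]]
  i2 <- unet_forward(m, list(x))$probs[[1]]
  expect_identical(i1, i2)
})

test_that("encoder transfer copies encoder and bottleneck weights only", {
  cfg <- mini_unet_config(64L)
  src <- build_unet(cfg, seed = 3)
  tgt <- build_unet(cfg, seed = 4)
  out <- transfer_encoder(src, tgt)
  rep <- attr(out, "transfer_report")
  expect_setequal(rep, grep("^(enc|bott)", names(src$params), value = TRUE))
  for (nm in rep) expect_identical(out$params[[nm]], src$params[[nm]])
  dec <- grep("^dec", names(tgt$params), value = TRUE)
  for (nm in dec) expect_identical(out$params[[nm]], tgt$params[[nm]])
  expect_false(identical(out$params$dec1_conv1, src$params$dec1_conv1))

  # encoder activations agree after transfer: probe via identical pooling
  # path by comparing full forward of two transferred copies
  o2 <- transfer_encoder(src, build_unet(cfg, seed = 5))
  x <- matrix(runif(64 * 64), 64, 64)
  # same encoder + different decoders: outputs differ, but transferring
  # the same source twice yields identical encoder parameters
  expect_identical(out$params$enc1_conv1, o2$params$enc1_conv1)

  other <- build_unet(unet_config(input_side = 64L,
                                  encoder_filters = c(4L, 16L),
                                  bottleneck_filters = 32L), seed = 1)
  expect_error(transfer_encoder(src, other), "mismatch")
})

test_that("predict_mask binarizes strictly and validates shape", {
  m <- build_unet(mini_unet_config(64L), seed = 6)
  x <- matrix(runif(64 * 64), 64, 64)
  pr <- predict_mask(m, x, threshold = 1.0)
  expect_equal(sum(pr$mask), 0)      # sigmoid < 1 everywhere
  pr2 <- predict_mask(m, x)
  expect_identical(pr2$mask, binarize_mask(pr2$prob, 0.5))
  expect_error(predict_mask(m, matrix(0.5, 32, 32)), "expects")
})

test_that("checkpoints round-trip through disk", {
  m <- build_unet(mini_unet_config(64L), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(unet_forward(m, list(x))$probs,
                   unet_forward(back, list(x))$probs)
})

test_that("backpropagation matches finite differences on a micro network", {
  cfg <- unet_config(input_side = 8L, encoder_filters = c(2L, 3L),
                     bottleneck_filters = 4L, dropout_rate = 0,
                     bottleneck_dropout = FALSE)
  m <- build_unet(cfg, seed = 3)
  set.seed(7)
  xs <- list(matrix(runif(64), 8, 8))
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  lc <- loss_config()
  loss_of <- function(model) {
    fw <- unet_forward(model, xs, training = TRUE)
    composite_loss(fw$probs[[1]], g, lc)
  }
  fw <- unet_forward(m, xs, training = TRUE, keep_cache = TRUE)
  p <- fw$probs[[1]]
  dlogits <- list(mammoseg:::composite_loss_grad(p, g, lc) * p * (1 - p))
  grads <- mammoseg:::unet_backward(m, fw$cache, dlogits)
  eps <- 1e-6
  set.seed(8)
  for (nm in c("enc1_conv1", "enc2_bn2", "bott_conv2", "dec2_tconv",
               "dec1_conv2", "head")) {
    pn <- names(grads[[nm]])[1]
    gmat <- grads[[nm]][[pn]]
    idx <- sample(length(gmat), 2)
    for (ii in idx) {
      m2 <- m; m2$params[[nm]][[pn]][ii] <- m2$params[[nm]][[pn]][ii] + eps
      m3 <- m; m3$params[[nm]][[pn]][ii] <- m3$params[[nm]][[pn]][ii] - eps
      fd <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      expect_lt(abs(gmat[ii] - fd) / max(1e-6, abs(fd) + abs(gmat[ii])),
                1e-4)
    }
  }
})
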