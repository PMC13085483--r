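#' Training configuration
#'
#' Adam optimization (learning rate 1e-4 by default) with early stopping,
#' learning-rate decay on plateau and best-checkpoint saving, all
#' monitored on the validation Dice score at threshold 0.5.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximal number of epochs.
#' @param early_stop_patience epochs without monitored improvement before
#'   stopping.
#' @param lr_decay_factor multiplicative decay applied on plateau.
#' @param lr_decay_patience epochs without improvement before decaying.
#' @param steps_per_epoch optional cap on training batches per epoch
#'   (samples are drawn without replacement per epoch up to the cap).
#' @param seed integer seed making the run reproducible.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         max_epochs = 30L, early_stop_patience = 10L,
                         lr_decay_factor = 0.5, lr_decay_patience = 5L,
                         steps_per_epoch = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            lr_decay_factor > 0, lr_decay_factor <= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_patience = as.integer(lr_decay_patience),
                 steps_per_epoch = steps_per_epoch,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split a dataset into train/validation/test partitions
#'
#' Random, disjoint, exhaustive and seed-reproducible. `spec` is either a
#' length-3 vector of fractions summing to 1 (sizes are rounded with the
#' largest-remainder rule) or explicit integer counts summing to
#' `length(items)` (accommodating printed cohort splits that do not follow
#' a standard rounding).
#'
#' @param items list or vector to partition.
#' @param spec fractions or explicit counts (train, validation, test).
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` (and the corresponding
#'   `*_idx` index vectors).
#' @export
split_dataset <- function(items, spec = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- length(items)
  if (length(spec) != 3) stop("spec must have 3 entries", call. = FALSE)
  if (all(spec == round(spec)) && sum(spec) > 1.5) {
    counts <- as.integer(spec)
    if (sum(counts) != n) {
      stop(sprintf("counts sum to %d but there are %d items",
                   sum(counts), n), call. = FALSE)
    }
  } else {
    if (abs(sum(spec) - 1) > 1e-9) {
      stop("fractions must sum to 1", call. = FALSE)
    }
    counts <- largest_remainder(n, spec)
  }
  ord <- with_seed(seed, sample.int(n))
  tr <- ord[seq_len(counts[1])]
  va <- ord[counts[1] + seq_len(counts[2])]
  te <- ord[counts[1] + counts[2] + seq_len(counts[3])]
  list(train = items[tr], validation = items[va], test = items[te],
       train_idx = tr, validation_idx = va, test_idx = te)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  list(m = rapply(params, zero_like, how = "replace"),
       v = rapply(params, zero_like, how = "replace"), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (!is.matrix(params[[nm]][[pn]])) g <- as.vector(g)
      opt$m[[nm]][[pn]] <- beta1 * opt$m[[nm]][[pn]] + (1 - beta1) * g
      opt$v[[nm]][[pn]] <- beta2 * opt$v[[nm]][[pn]] + (1 - beta2) * g^2
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        lr * (opt$m[[nm]][[pn]] / bc1) / (sqrt(opt$v[[nm]][[pn]] / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}

# map grads (W of conv layers come back named dW/db from C++) - normalize
rename_grad <- function(g) {
  if (!is.null(g$W)) list(W = g$W, b = g$b) else g
}

# ---- training loop ----------------------------------------------------------

validate_model <- function(model, val_samples, loss_cfg) {
  n <- length(val_samples)
  dice <- numeric(n); iou <- numeric(n); loss <- numeric(n)
  for (k in seq_len(n)) {
    s <- val_samples[[k]]
    fw <- unet_forward(model, list(s$image), training = FALSE)
    p <- fw$probs[[1]]
    pm <- binarize_mask(p, 0.5)
    gm <- binarize_mask(s$mask + 0, 0.5)
    dice[k] <- dice_coef(pm, gm)
    iou[k] <- iou_coef(pm, gm)
    loss[k] <- composite_loss(p, s$mask, loss_cfg)
  }
  list(dice = mean(dice), iou = mean(iou), loss = mean(loss))
}

maybe_flip <- function(s) {
  if (runif(1) < 0.5) {
    s$image <- s$image[, rev(seq_len(ncol(s$image)))]
    s$mask <- s$mask[, rev(seq_len(ncol(s$mask)))]
  }
  if (runif(1) < 0.5) {
    s$image <- s$image[rev(seq_len(nrow(s$image))), ]
    s$mask <- s$mask[rev(seq_len(nrow(s$mask))), ]
  }
  s
}

# Core loop shared by both stages. `draw_epoch` returns the list of
# training samples for one epoch (each a list(image, mask)).
run_training <- function(model, draw_epoch, n_train, val_samples, loss_cfg,
                         cfg, flip_augment = FALSE, verbose = FALSE) {
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    lr <- cfg$learning_rate
    best <- -Inf
    best_model <- model
    best_epoch <- 0L
    wait_stop <- 0L; wait_lr <- 0L
    hist <- list()
    stop_reason <- "max_epochs"
    for (epoch in seq_len(cfg$max_epochs)) {
      samples <- draw_epoch()
      if (!is.null(cfg$steps_per_epoch)) {
        samples <- samples[seq_len(min(length(samples),
                                       cfg$steps_per_epoch * cfg$batch_size))]
      }
      if (flip_augment) samples <- lapply(samples, maybe_flip)
      nb <- ceiling(length(samples) / cfg$batch_size)
      ep_loss <- 0; ep_dice <- 0; ns <- 0
      for (bi in seq_len(nb)) {
        idx <- ((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size,
                                                   length(samples))
        xs <- lapply(samples[idx], `[[`, "image")
        gts <- lapply(samples[idx], `[[`, "mask")
        fw <- unet_forward(model, xs, training = TRUE, keep_cache = TRUE)
        model$state <- fw$state
        dlogits <- vector("list", length(idx))
        for (k in seq_along(idx)) {
          p <- fw$probs[[k]]
          g <- gts[[k]]
          ep_loss <- ep_loss + composite_loss(p, g, loss_cfg)
          ep_dice <- ep_dice + dice_coef(binarize_mask(p, 0.5),
                                         binarize_mask(g + 0, 0.5))
          dLdp <- composite_loss_grad(p, g, loss_cfg)
          dlogits[[k]] <- dLdp * p * (1 - p) / length(idx)
        }
        ns <- ns + length(idx)
        grads <- unet_backward(model, fw$cache, dlogits)
        grads <- lapply(grads, rename_grad)
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$opt
      }
      val <- validate_model(model, val_samples, loss_cfg)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = ep_loss / ns,
                                  train_dice = ep_dice / ns,
                                  val_loss = val$loss, val_dice = val$dice,
                                  val_iou = val$iou)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train loss %.4f  val dice %.4f",
                        epoch, lr, ep_loss / ns, val$dice))
      }
      if (val$dice > best + 1e-9) {
        best <- val$dice
        best_model <- model
        best_epoch <- epoch
        wait_stop <- 0L; wait_lr <- 0L
      } else {
        wait_stop <- wait_stop + 1L
        wait_lr <- wait_lr + 1L
        if (wait_lr >= cfg$lr_decay_patience) {
          lr <- lr * cfg$lr_decay_factor
          wait_lr <- 0L
        }
        if (wait_stop >= cfg$early_stop_patience) {
          stop_reason <- "early_stopping"
          break
        }
      }
    }
    history <- do.call(rbind, hist)
    attr(history, "checkpoint_epoch") <- best_epoch
    attr(history, "best_val_dice") <- best
    attr(history, "stop_reason") <- stop_reason
    list(model = best_model, history = history)
  })
}

#' Stage 1: pretrain on lesion-centered patches
#'
#' Trains the model on the patch dataset (positives and negatives) with
#' stochastic horizontal/vertical flip augmentation, Adam, early
#' stopping, learning-rate decay and best-validation-Dice checkpointing.
#'
#' @param model a `unet_model` whose `input_side` matches the patch side.
#' @param patch_train,patch_val patch lists from [build_patch_dataset()].
#' @param loss_cfg a [loss_config()].
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint) and `history` (data frame
#'   with attributes `checkpoint_epoch`, `best_val_dice`, `stop_reason`).
#' @export
pretrain_on_patches <- function(model, patch_train, patch_val,
                                loss_cfg = loss_config(),
                                config = train_config(), verbose = FALSE) {
  if (length(patch_train) == 0) stop("empty training split", call. = FALSE)
  if (length(patch_val) == 0) stop("empty validation split", call. = FALSE)
  to_sample <- function(p) list(image = p$image_crop, mask = p$mask_crop + 0)
  train_s <- lapply(patch_train, to_sample)
  val_s <- lapply(patch_val, to_sample)
  draw_epoch <- function() train_s[sample.int(length(train_s))]
  run_training(model, draw_epoch, length(train_s), val_s, loss_cfg, config,
               flip_augment = TRUE, verbose = verbose)
}

#' Stage 2: fine-tune on full images with hybrid patch substitution
#'
#' Builds a fresh model with the same architecture, transfers the
#' pretrained encoder and bottleneck weights via [transfer_encoder()],
#' and fine-tunes on full (model-resolution) images where each training
#' sample is, with probability `sampler_cfg$hybrid_substitution_prob`,
#' replaced by a positive lesion patch. Validation uses full images only.
#'
#' @param pretrained the Stage-1 `unet_model`.
#' @param full_train,full_val lists of model-resolution [image_pair()]s.
#' @param patch_pool patch list providing the substitution pool.
#' @param loss_cfg a [loss_config()].
#' @param config a [train_config()].
#' @param sampler_cfg a [sampler_config()] (substitution probability).
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history`, as for
#'   [pretrain_on_patches()].
#' @export
finetune_full_images <- function(pretrained, full_train, full_val, patch_pool,
                                 loss_cfg = loss_config(),
                                 config = train_config(),
                                 sampler_cfg = sampler_config(),
                                 verbose = FALSE) {
  if (length(full_train) == 0) stop("empty training split", call. = FALSE)
  if (length(full_val) == 0) stop("empty validation split", call. = FALSE)
  target <- build_unet(pretrained$config, seed = config$seed + 1L)
  target <- transfer_encoder(pretrained, target)
  sampler <- hybrid_sampler(full_train, patch_pool, sampler_cfg)
  val_s <- lapply(full_val, function(p) list(image = p$image,
                                             mask = p$mask + 0))
  n <- length(full_train)
  draw_epoch <- function() {
    lapply(sampler(n), function(s) list(image = s$image, mask = s$mask + 0,
                                        source = s$source))
  }
  run_training(target, draw_epoch, n, val_s, loss_cfg, config,
               flip_augment = FALSE, verbose = verbose)
}

#' Write a training history CSV and Figure-style curve panels
#'
#' Writes `history.csv` plus a three-panel PNG (loss, Dice, IoU curves
#' for training and validation).
#'
#' @param history history data frame from a training run.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_history <- function(history, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(history, file.path(dir, "history.csv"), row.names = FALSE)
  grDevices::png(file.path(dir, "curves.png"), width = 1200, height = 400)
  graphics::par(mfrow = c(1, 3))
  graphics::matplot(history$epoch, cbind(history$train_loss, history$val_loss),
                    type = "l", lty = 1, col = c("blue", "orange"),
                    xlab = "epoch", ylab = "loss", main = "Loss")
  graphics::legend("topright", c("train", "val"), col = c("blue", "orange"),
                   lty = 1)
  graphics::matplot(history$epoch, cbind(history$train_dice, history$val_dice),
                    type = "l", lty = 1, col = c("blue", "orange"),
                    xlab = "epoch", ylab = "Dice", main = "Dice")
  graphics::plot(history$epoch, history$val_iou, type = "l", col = "orange",
                 xlab = "epoch", ylab = "IoU", main = "Validation IoU")
  grDevices::dev.off()
  invisible(dir)
}
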