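#' Resolve a workbench run configuration
#'
#' Merges a YAML configuration (sections `phantom:`, `preprocess:`,
#' `sampler:`, `model:`, `loss:`, `train:`, `eval:` plus top-level `seed`
#' and `out`) over the package defaults. The resolved configuration is
#' written into the run directory so a run can be reproduced
#' bit-identically.
#'
#' @param path optional YAML file path.
#' @param overrides optional named list merged last (same structure).
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    out = "runs/run1",
    phantom = list(n_images = 32L, image_side = 512L,
                   size_mix = c(37, 13, 5) / 55),
    preprocess = list(clahe_clip_limit = 2.0, clahe_tile_grid = 8L,
                      target_side = 224L, mask_threshold = 0.5),
    sampler = list(patch_side = 224L, neg_per_pos = 2L,
                   neg_max_coverage = 0.05, centroid_jitter_frac = 0.25,
                   split_train_frac = 0.8, hybrid_substitution_prob = 0.35),
    model = list(input_side = 224L, encoder_filters = c(8L, 16L, 32L),
                 bottleneck_filters = 64L, dropout_rate = 0.3),
    loss = list(focal_gamma = 2, focal_alpha = 0.25, tversky_alpha = 0.3,
                tversky_beta = 0.7, mix_focal = 1, mix_tversky = 1),
    train = list(learning_rate = 1e-4, batch_size = 8L, max_epochs = 15L,
                 early_stop_patience = 10L, lr_decay_factor = 0.5,
                 lr_decay_patience = 5L, split = c(0.6, 0.2, 0.2)),
    eval = list(detection_threshold = 0.10, bounds = c(500, 1500),
                area_basis = "native"))
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_lists(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    cfg <- merge_lists(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_lists(cfg, overrides)
  structure(cfg, class = "run_config")
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact '%s' (run `%s` first)",
                 path, producer), call. = FALSE)
  }
  path
}

snapshot_config <- function(cfg, stage) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out, "config_resolved.yaml"))
  logf <- file.path(cfg$out, paste0(stage, ".log"))
  function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
}

#' Workbench stage: simulate a synthetic cohort
#'
#' Writes `cohort/images/`, `cohort/masks/` and `cohort/manifest.csv`
#' under the run directory.
#'
#' @param cfg a [run_config()].
#' @return the cohort, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  log <- snapshot_config(cfg, "simulate")
  co <- generate_cohort(cfg$phantom$n_images,
                        size_mix = cfg$phantom$size_mix,
                        seed = cfg$seed,
                        image_side = cfg$phantom$image_side)
  write_cohort(co, file.path(cfg$out, "cohort"))
  log("simulated %d phantom pairs at side %d", cfg$phantom$n_images,
      cfg$phantom$image_side)
  invisible(co)
}

#' Workbench stage: preprocess the cohort and fix the data split
#'
#' Normalizes and CLAHE-enhances every image at native resolution, stores
#' the model-resolution resized pairs, and writes the train/validation/
#' test split assignment.
#'
#' @param cfg a [run_config()].
#' @return list of preprocessed native pairs, invisibly.
#' @export
cmd_preprocess <- function(cfg) {
  log <- snapshot_config(cfg, "preprocess")
  co <- read_cohort(require_artifact(file.path(cfg$out, "cohort"),
                                     "cmd_simulate"))
  pcfg <- do.call(preprocess_config, cfg$preprocess)
  native <- lapply(co$pairs, function(p) {
    image_pair(p$id, normalize_and_enhance(p$image, pcfg), p$mask,
               native_side = p$native_side)
  })
  saveRDS(native, file.path(cfg$out, "preprocessed_native.rds"))
  model_res <- lapply(native, resize_pair, target_side = pcfg$target_side,
                      method = pcfg$resize_method)
  saveRDS(model_res, file.path(cfg$out, "preprocessed_model.rds"))
  sp <- split_dataset(vapply(native, `[[`, character(1), "id"),
                      spec = cfg$train$split, seed = cfg$seed)
  split_df <- data.frame(
    id = c(sp$train, sp$validation, sp$test),
    split = rep(c("train", "validation", "test"),
                c(length(sp$train), length(sp$validation), length(sp$test))))
  write.csv(split_df, file.path(cfg$out, "split.csv"), row.names = FALSE)
  log("preprocessed %d pairs; split %d/%d/%d", length(native),
      length(sp$train), length(sp$validation), length(sp$test))
  invisible(native)
}

load_stage_data <- function(cfg) {
  native <- readRDS(require_artifact(
    file.path(cfg$out, "preprocessed_native.rds"), "cmd_preprocess"))
  model_res <- readRDS(require_artifact(
    file.path(cfg$out, "preprocessed_model.rds"), "cmd_preprocess"))
  split_df <- read.csv(require_artifact(file.path(cfg$out, "split.csv"),
                                        "cmd_preprocess"),
                       stringsAsFactors = FALSE)
  ids <- vapply(native, `[[`, character(1), "id")
  of_split <- function(lst, s) {
    lst[ids %in% split_df$id[split_df$split == s]]
  }
  list(native = native, model_res = model_res, split_df = split_df,
       of_split = of_split)
}

build_stage_patches <- function(cfg, data) {
  scfg <- do.call(sampler_config, c(cfg$sampler, list(seed = cfg$seed)))
  build_patch_dataset(data$of_split(data$native, "train"), scfg)
}

#' Workbench stage: Stage-1 patch pretraining
#'
#' @param cfg a [run_config()].
#' @return the training result, invisibly.
#' @export
cmd_pretrain <- function(cfg) {
  log <- snapshot_config(cfg, "pretrain")
  data <- load_stage_data(cfg)
  patches <- build_stage_patches(cfg, data)
  ucfg <- do.call(unet_config, cfg$model)
  model <- build_unet(ucfg, seed = cfg$seed)
  tcfg <- do.call(train_config,
                  c(cfg$train[setdiff(names(cfg$train), "split")],
                    list(seed = cfg$seed)))
  res <- pretrain_on_patches(model, patches$train, patches$validation,
                             do.call(loss_config, cfg$loss), tcfg)
  dir.create(file.path(cfg$out, "stage1"), showWarnings = FALSE)
  save_checkpoint(res$model, file.path(cfg$out, "stage1", "checkpoint.rds"))
  write_history(res$history, file.path(cfg$out, "stage1"))
  log("stage 1 done: best val dice %.4f at epoch %d",
      attr(res$history, "best_val_dice"),
      attr(res$history, "checkpoint_epoch"))
  invisible(res)
}

#' Workbench stage: Stage-2 full-image fine-tuning
#'
#' @param cfg a [run_config()].
#' @return the training result, invisibly.
#' @export
cmd_finetune <- function(cfg) {
  log <- snapshot_config(cfg, "finetune")
  data <- load_stage_data(cfg)
  pre <- load_checkpoint(require_artifact(
    file.path(cfg$out, "stage1", "checkpoint.rds"), "cmd_pretrain"))
  patches <- build_stage_patches(cfg, data)
  scfg <- do.call(sampler_config, c(cfg$sampler, list(seed = cfg$seed)))
  tcfg <- do.call(train_config,
                  c(cfg$train[setdiff(names(cfg$train), "split")],
                    list(seed = cfg$seed)))
  res <- finetune_full_images(pre, data$of_split(data$model_res, "train"),
                              data$of_split(data$model_res, "validation"),
                              patches$train,
                              do.call(loss_config, cfg$loss), tcfg, scfg)
  dir.create(file.path(cfg$out, "stage2"), showWarnings = FALSE)
  save_checkpoint(res$model, file.path(cfg$out, "stage2", "checkpoint.rds"))
  write_history(res$history, file.path(cfg$out, "stage2"))
  log("stage 2 done: best val dice %.4f at epoch %d",
      attr(res$history, "best_val_dice"),
      attr(res$history, "checkpoint_epoch"))
  invisible(res)
}

#' Workbench stage: evaluate the fine-tuned model on the test split
#'
#' @param cfg a [run_config()].
#' @return the evaluation records, invisibly.
#' @export
cmd_evaluate <- function(cfg) {
  log <- snapshot_config(cfg, "evaluate")
  data <- load_stage_data(cfg)
  model <- load_checkpoint(require_artifact(
    file.path(cfg$out, "stage2", "checkpoint.rds"), "cmd_finetune"))
  test_pairs <- data$of_split(data$model_res, "test")
  if (length(test_pairs) == 0) stop("empty test split", call. = FALSE)
  rec <- evaluate_test_set(model, test_pairs,
                           detection_threshold = cfg$eval$detection_threshold,
                           bounds = cfg$eval$bounds,
                           area_basis = cfg$eval$area_basis)
  write_records_csv(rec, file.path(cfg$out, "records.csv"))
  log("evaluated %d test images; %d detected", nrow(rec), sum(rec$detected))
  invisible(rec)
}

#' Workbench stage: render the report tables and overlays
#'
#' @param cfg a [run_config()].
#' @return the stratified report, invisibly.
#' @export
cmd_report <- function(cfg) {
  log <- snapshot_config(cfg, "report")
  rec <- read.csv(require_artifact(file.path(cfg$out, "records.csv"),
                                   "cmd_evaluate"), stringsAsFactors = FALSE)
  class(rec) <- c("eval_records", "data.frame")
  rep <- stratify_records(rec, bounds = cfg$eval$bounds)
  write_report_tables(rec, rep, file.path(cfg$out, "report"))
  data <- load_stage_data(cfg)
  model <- load_checkpoint(file.path(cfg$out, "stage2", "checkpoint.rds"))
  dir.create(file.path(cfg$out, "report", "overlays"), showWarnings = FALSE)
  for (pair in head(data$of_split(data$model_res, "test"), 6)) {
    pm <- predict_mask(model, pair$image)$mask
    write_overlay_png(pair, pm, file.path(cfg$out, "report", "overlays",
                                          paste0(pair$id, ".png")))
  }
  log("report written to %s", file.path(cfg$out, "report"))
  invisible(rep)
}
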