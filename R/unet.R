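#' U-Net architecture configuration
#'
#' The default configuration is the enhanced U-Net used throughout:
#' a three-level encoder with 64/128/256 filters (two 3 x 3 convolutions,
#' batch normalization and ReLU per block, 2 x 2 max-pooling, dropout 0.3
#' at each downsampling stage), a 512-filter bottleneck, a transpose-
#' convolution decoder with skip concatenation, and a 1-channel sigmoid
#' head. Scaled-down widths (e.g. 8/16/32 with a 64-filter bottleneck)
#' give a desk-scale network with identical topology.
#'
#' @param input_side input resolution; must be divisible by
#'   `2^length(encoder_filters)`.
#' @param encoder_filters strictly increasing integer vector of per-level
#'   filter counts.
#' @param bottleneck_filters bottleneck width.
#' @param dropout_rate dropout rate applied at each downsampling stage.
#' @param bottleneck_dropout also apply dropout after the bottleneck.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(input_side = 224L, encoder_filters = c(64L, 128L, 256L),
                        bottleneck_filters = 512L, dropout_rate = 0.3,
                        bottleneck_dropout = TRUE) {
  if (any(diff(encoder_filters) <= 0)) {
    stop("encoder_filters must be strictly increasing", call. = FALSE)
  }
  depth <- length(encoder_filters)
  if (input_side %% 2^depth != 0) {
    stop(sprintf("input_side %d not divisible by 2^%d", input_side, depth),
         call. = FALSE)
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_side = as.integer(input_side),
                 encoder_filters = as.integer(encoder_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 dropout_rate = dropout_rate,
                 bottleneck_dropout = isTRUE(bottleneck_dropout)),
            class = "unet_config")
}

he_uniform <- function(fan_in, n_rows, n_cols) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(n_rows * n_cols, -lim, lim), n_rows, n_cols)
}

new_conv3 <- function(cin, cout) list(W = he_uniform(9 * cin, 9 * cin, cout),
                                      b = numeric(cout))
new_conv1 <- function(cin, cout) list(W = he_uniform(cin, cin, cout),
                                      b = numeric(cout))
new_tconv2 <- function(cin, cout) list(W = he_uniform(4 * cin, 4 * cin, cout),
                                       b = numeric(cout))
new_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))
new_bn_state <- function(c) list(rmean = numeric(c), rvar = rep(1, c))

#' Build a U-Net model
#'
#' Initializes all parameters (He-uniform weights, unit-gamma batch norm)
#' deterministically from `seed`. The returned handle carries the
#' trainable parameters, the batch-norm running statistics and a
#' per-layer parameter manifest.
#'
#' @param config a [unet_config()].
#' @param seed integer initialization seed.
#' @return object of class `unet_model` with fields `config`, `params`,
#'   `state`, `manifest` and `n_params`.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  with_seed(seed, {
    f <- config$encoder_filters
    d <- length(f)
    B <- config$bottleneck_filters
    params <- list()
    state <- list()
    cin <- 1L
    for (i in seq_len(d)) {
      params[[sprintf("enc%d_conv1", i)]] <- new_conv3(cin, f[i])
      params[[sprintf("enc%d_bn1", i)]] <- new_bn(f[i])
      params[[sprintf("enc%d_conv2", i)]] <- new_conv3(f[i], f[i])
      params[[sprintf("enc%d_bn2", i)]] <- new_bn(f[i])
      state[[sprintf("enc%d_bn1", i)]] <- new_bn_state(f[i])
      state[[sprintf("enc%d_bn2", i)]] <- new_bn_state(f[i])
      cin <- f[i]
    }
    params[["bott_conv1"]] <- new_conv3(f[d], B)
    params[["bott_bn1"]] <- new_bn(B)
    params[["bott_conv2"]] <- new_conv3(B, B)
    params[["bott_bn2"]] <- new_bn(B)
    state[["bott_bn1"]] <- new_bn_state(B)
    state[["bott_bn2"]] <- new_bn_state(B)
    up_in <- B
    for (i in rev(seq_len(d))) {
      params[[sprintf("dec%d_tconv", i)]] <- new_tconv2(up_in, f[i])
      params[[sprintf("dec%d_conv1", i)]] <- new_conv3(2L * f[i], f[i])
      params[[sprintf("dec%d_bn1", i)]] <- new_bn(f[i])
      params[[sprintf("dec%d_conv2", i)]] <- new_conv3(f[i], f[i])
      params[[sprintf("dec%d_bn2", i)]] <- new_bn(f[i])
      state[[sprintf("dec%d_bn1", i)]] <- new_bn_state(f[i])
      state[[sprintf("dec%d_bn2", i)]] <- new_bn_state(f[i])
      up_in <- f[i]
    }
    params[["head"]] <- new_conv1(f[1], 1L)
    manifest <- do.call(rbind, lapply(names(params), function(nm) {
      do.call(rbind, lapply(names(params[[nm]]), function(pn) {
        p <- params[[nm]][[pn]]
        data.frame(layer = nm, param = pn,
                   shape = paste(if (is.matrix(p)) dim(p) else length(p),
                                 collapse = "x"),
                   count = length(p), stringsAsFactors = FALSE)
      }))
    }))
    structure(list(config = config, params = params, state = state,
                   manifest = manifest, n_params = sum(manifest$count)),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  f <- x$config$encoder_filters
  cat(sprintf("<unet_model> input %d, encoder [%s], bottleneck %d, %d parameters\n",
              x$config$input_side, paste(f, collapse = ", "),
              x$config$bottleneck_filters, x$n_params))
  invisible(x)
}

# ---- fused batch-norm + ReLU over a batch of (H, W, C) activations ----------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bnrelu_fwd_batch <- function(Zs, par, st, training) {
  C <- dim(Zs[[1]])[3]
  if (training) {
    mom <- Reduce(`+`, lapply(Zs, bn_moments))
    n <- sum(vapply(Zs, function(Z) prod(dim(Z)[1:2]), numeric(1)))
    mu <- mom[, 1] / n
    va <- pmax(mom[, 2] / n - mu^2, 0)
    st$rmean <- (1 - BN_MOMENTUM) * st$rmean + BN_MOMENTUM * mu
    st$rvar <- (1 - BN_MOMENTUM) * st$rvar + BN_MOMENTUM * va
  } else {
    mu <- st$rmean; va <- st$rvar
  }
  istd <- 1 / sqrt(va + BN_EPS)
  xhats <- vector("list", length(Zs))
  As <- vector("list", length(Zs))
  for (k in seq_along(Zs)) {
    r <- bnrelu_fwd(Zs[[k]], mu, istd, par$gamma, par$beta)
    xhats[[k]] <- r$xhat
    As[[k]] <- r$A
  }
  list(As = As, cache = list(xhats = xhats, As = As, istd = istd), state = st)
}

bnrelu_bwd_batch <- function(dAs, par, cache) {
  S <- Reduce(`+`, mapply(bnrelu_bwd_sums, dAs, cache$As, cache$xhats,
                          SIMPLIFY = FALSE))
  dbeta <- S[, 1]
  dgamma <- S[, 2]
  n <- sum(vapply(dAs, function(d) prod(dim(d)[1:2]), numeric(1)))
  mean_dxhat <- par$gamma * dbeta / n
  mean_dxhat_xhat <- par$gamma * dgamma / n
  dZs <- mapply(function(dA, A, xh) {
    bnrelu_bwd(dA, A, xh, par$gamma, cache$istd, mean_dxhat, mean_dxhat_xhat)
  }, dAs, cache$As, cache$xhats, SIMPLIFY = FALSE)
  list(dZs = dZs, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(Xs, rate, training) {
  if (!training || rate <= 0) return(list(Ys = Xs, masks = NULL))
  masks <- lapply(Xs, function(X) {
    array(runif(length(X)) >= rate, dim(X)) / (1 - rate)
  })
  list(Ys = mapply(function(X, m) X * m, Xs, masks, SIMPLIFY = FALSE),
       masks = masks)
}
dropout_bwd <- function(dYs, masks) {
  if (is.null(masks)) return(dYs)
  mapply(function(dY, m) dY * m, dYs, masks, SIMPLIFY = FALSE)
}

concat_c <- function(A, B) {
  dims <- dim(A)
  out <- array(0, c(dims[1], dims[2], dims[3] + dim(B)[3]))
  out[, , seq_len(dims[3])] <- A
  out[, , dims[3] + seq_len(dim(B)[3])] <- B
  out
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

#' Forward pass over a batch of images
#'
#' @param model a `unet_model`.
#' @param xs list of input matrices (`input_side` x `input_side`) or
#'   single-channel arrays.
#' @param training logical; enables batch statistics and dropout (uses the
#'   current RNG stream) and updates running statistics in the returned
#'   model state.
#' @param keep_cache keep intermediate activations for [unet_backward()].
#' @return list with `probs` (list of probability matrices), `logits`,
#'   `cache` (when requested) and `state` (updated running statistics).
#' @export
unet_forward <- function(model, xs, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  P <- model$params
  st <- model$state
  d <- length(cfg$encoder_filters)
  cache <- if (keep_cache) list() else NULL
  keep <- function(nm, val) if (keep_cache) cache[[nm]] <<- val
  Xs <- lapply(xs, as_cube)

  skips <- vector("list", d)
  for (i in seq_len(d)) {
    for (j in 1:2) {
      cname <- sprintf("enc%d_conv%d", i, j)
      bname <- sprintf("enc%d_bn%d", i, j)
      keep(paste0(cname, "_in"), Xs)
      Zs <- lapply(Xs, function(X) conv3_fwd(X, P[[cname]]$W, P[[cname]]$b))
      bn <- bnrelu_fwd_batch(Zs, P[[bname]], st[[bname]], training)
      st[[bname]] <- bn$state
      keep(paste0(bname, "_cache"), bn$cache)
      Xs <- bn$As
    }
    skips[[i]] <- Xs
    pool <- lapply(Xs, pool2_fwd)
    keep(sprintf("enc%d_poolidx", i), lapply(pool, `[[`, "idx"))
    keep(sprintf("enc%d_pooldim", i), dim(Xs[[1]]))
    Xs <- lapply(pool, `[[`, "Y")
    dr <- dropout_fwd(Xs, cfg$dropout_rate, training)
    keep(sprintf("enc%d_dropmask", i), dr$masks)
    Xs <- dr$Ys
  }
  for (j in 1:2) {
    cname <- sprintf("bott_conv%d", j)
    bname <- sprintf("bott_bn%d", j)
    keep(paste0(cname, "_in"), Xs)
    Zs <- lapply(Xs, function(X) conv3_fwd(X, P[[cname]]$W, P[[cname]]$b))
    bn <- bnrelu_fwd_batch(Zs, P[[bname]], st[[bname]], training)
    st[[bname]] <- bn$state
    keep(paste0(bname, "_cache"), bn$cache)
    Xs <- bn$As
  }
  if (cfg$bottleneck_dropout) {
    dr <- dropout_fwd(Xs, cfg$dropout_rate, training)
    keep("bott_dropmask", dr$masks)
    Xs <- dr$Ys
  }
  for (i in rev(seq_len(d))) {
    tname <- sprintf("dec%d_tconv", i)
    keep(paste0(tname, "_in"), Xs)
    Us <- lapply(Xs, function(X) tconv2_fwd(X, P[[tname]]$W, P[[tname]]$b))
    Xs <- mapply(concat_c, Us, skips[[i]], SIMPLIFY = FALSE)
    for (j in 1:2) {
      cname <- sprintf("dec%d_conv%d", i, j)
      bname <- sprintf("dec%d_bn%d", i, j)
      keep(paste0(cname, "_in"), Xs)
      Zs <- lapply(Xs, function(X) conv3_fwd(X, P[[cname]]$W, P[[cname]]$b))
      bn <- bnrelu_fwd_batch(Zs, P[[bname]], st[[bname]], training)
      st[[bname]] <- bn$state
      keep(paste0(bname, "_cache"), bn$cache)
      Xs <- bn$As
    }
  }
  keep("head_in", Xs)
  logits <- lapply(Xs, function(X) conv1_fwd(X, P$head$W, P$head$b))
  probs <- lapply(logits, function(L) {
    p <- 1 / (1 + exp(-L[, , 1]))
    p
  })
  list(probs = probs, logits = logits, cache = cache, state = st)
}

# Backward pass: dlogits is a list of (H, W) matrices of dL/dlogit.
# Returns gradients named like `model$params`.
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  P <- model$params
  d <- length(cfg$encoder_filters)
  grads <- list()
  g_add <- function(nm, dW, db) {
    grads[[nm]] <<- list(W = dW, b = db)
  }
  dXs <- lapply(dlogits, function(dl) array(dl, c(nrow(dl), ncol(dl), 1L)))

  # head
  acc_dW <- NULL; acc_db <- NULL
  dPrev <- vector("list", length(dXs))
  for (k in seq_along(dXs)) {
    bw <- conv1_bwd(cache$head_in[[k]], P$head$W, dXs[[k]])
    dPrev[[k]] <- bw$dX
    acc_dW <- if (is.null(acc_dW)) bw$dW else acc_dW + bw$dW
    acc_db <- if (is.null(acc_db)) bw$db else acc_db + bw$db
  }
  g_add("head", acc_dW, acc_db)
  dXs <- dPrev

  conv_block_bwd <- function(cname, bname, dXs, need_dx = TRUE) {
    bn <- bnrelu_bwd_batch(dXs, P[[bname]], cache[[paste0(bname, "_cache")]])
    grads[[bname]] <<- list(gamma = bn$dgamma, beta = bn$dbeta)
    ins <- cache[[paste0(cname, "_in")]]
    acc_dW <- NULL; acc_db <- NULL
    out <- vector("list", length(dXs))
    for (k in seq_along(dXs)) {
      bw <- conv3_bwd(ins[[k]], P[[cname]]$W, bn$dZs[[k]], need_dx)
      out[[k]] <- bw$dX
      acc_dW <- if (is.null(acc_dW)) bw$dW else acc_dW + bw$dW
      acc_db <- if (is.null(acc_db)) bw$db else acc_db + bw$db
    }
    grads[[cname]] <<- list(W = acc_dW, b = acc_db)
    out
  }

  dSkips <- vector("list", d)
  for (i in seq_len(d)) {   # decoder blocks, shallowest first = reverse order
    for (j in 2:1) {
      dXs <- conv_block_bwd(sprintf("dec%d_conv%d", i, j),
                            sprintf("dec%d_bn%d", i, j), dXs)
    }
    fi <- cfg$encoder_filters[i]
    dUs <- lapply(dXs, function(dX) dX[, , seq_len(fi), drop = FALSE])
    dSkips[[i]] <- lapply(dXs, function(dX) {
      dX[, , fi + seq_len(dim(dX)[3] - fi), drop = FALSE]
    })
    tname <- sprintf("dec%d_tconv", i)
    ins <- cache[[paste0(tname, "_in")]]
    acc_dW <- NULL; acc_db <- NULL
    dPrev <- vector("list", length(dUs))
    for (k in seq_along(dUs)) {
      bw <- tconv2_bwd(ins[[k]], P[[tname]]$W, as_cube(dUs[[k]]))
      dPrev[[k]] <- bw$dX
      acc_dW <- if (is.null(acc_dW)) bw$dW else acc_dW + bw$dW
      acc_db <- if (is.null(acc_db)) bw$db else acc_db + bw$db
    }
    g_add(tname, acc_dW, acc_db)
    dXs <- dPrev
  }

  if (cfg$bottleneck_dropout) dXs <- dropout_bwd(dXs, cache$bott_dropmask)
  for (j in 2:1) {
    dXs <- conv_block_bwd(sprintf("bott_conv%d", j),
                          sprintf("bott_bn%d", j), dXs)
  }

  for (i in rev(seq_len(d))) {
    dXs <- dropout_bwd(dXs, cache[[sprintf("enc%d_dropmask", i)]])
    idx <- cache[[sprintf("enc%d_poolidx", i)]]
    dims <- cache[[sprintf("enc%d_pooldim", i)]]
    dXs <- mapply(function(dY, ix) pool2_bwd(dY, ix, dims[1], dims[2]),
                  dXs, idx, SIMPLIFY = FALSE)
    dXs <- mapply(`+`, dXs, dSkips[[i]], SIMPLIFY = FALSE)
    for (j in 2:1) {
      dXs <- conv_block_bwd(sprintf("enc%d_conv%d", i, j),
                            sprintf("enc%d_bn%d", i, j), dXs,
                            need_dx = !(i == 1 && j == 1))
    }
  }
  grads
}

#' Transfer encoder (and bottleneck) weights between models
#'
#' Copies every encoder-block and bottleneck parameter - including batch
#' norm running statistics - from `source` into `target`, leaving the
#' decoder and head untouched. The encoder architectures must be
#' identical.
#'
#' @param source,target `unet_model` objects.
#' @return `target` with transferred weights; the copied layer names are
#'   attached as attribute `"transfer_report"`.
#' @export
transfer_encoder <- function(source, target) {
  stopifnot(inherits(source, "unet_model"), inherits(target, "unet_model"))
  enc_layers <- grep("^(enc|bott)", names(source$params), value = TRUE)
  copied <- character(0)
  for (nm in enc_layers) {
    if (is.null(target$params[[nm]])) {
      stop(sprintf("architecture mismatch: target lacks layer '%s'", nm),
           call. = FALSE)
    }
    src <- source$params[[nm]]; tgt <- target$params[[nm]]
    for (pn in names(src)) {
      if (!identical(dim(src[[pn]]), dim(tgt[[pn]])) ||
          length(src[[pn]]) != length(tgt[[pn]])) {
        stop(sprintf("architecture mismatch at layer '%s' (parameter '%s')",
                     nm, pn), call. = FALSE)
      }
    }
    target$params[[nm]] <- src
    if (!is.null(source$state[[nm]])) {
      target$state[[nm]] <- source$state[[nm]]
    }
    copied <- c(copied, nm)
  }
  attr(target, "transfer_report") <- copied
  target
}

#' Predict a lesion probability map and binary mask for one image
#'
#' Runs an inference-mode forward pass (dropout off, running batch-norm
#' statistics) and binarizes the probability map with a strict threshold.
#'
#' @param model a `unet_model`.
#' @param image matrix matching the model's `input_side`.
#' @param threshold binarization threshold (default 0.5).
#' @return list with `prob` (matrix in (0, 1)) and `mask` (0/1 matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  side <- model$config$input_side
  if (!identical(dim(image), c(side, side))) {
    stop(sprintf("image is %s, model expects %d x %d",
                 paste(dim(image), collapse = " x "), side, side),
         call. = FALSE)
  }
  fw <- unet_forward(model, list(image), training = FALSE)
  prob <- fw$probs[[1]]
  list(prob = prob, mask = binarize_mask(prob, threshold))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS snapshots of the model handle
#' (architecture config, trainable parameters, batch-norm state).
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @return `path` (save) or the restored `unet_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model[c("config", "params", "state", "manifest", "n_params")], path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "unet_model")
}
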