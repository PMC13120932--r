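# Full model: backbone -> stain suppression (optional) -> spatial head.
#
# The model object bundles the backbone handle, SDA and head parameters and
# all configuration. Forward/backward passes are hand-derived matrix
# calculus, verified against finite differences in the test suite.

#' Build a stain-robust MIL classification model
#'
#' @param side input image side in pixels (images are resized to this).
#' @param backbone a backbone handle; default [backbone_mini()].
#' @param sda_window window size of the SDA attention branch (default 7).
#' @param head config list from [head_config()].
#' @param ablate_sda if TRUE the stain-suppression module is replaced by the
#'   identity (backbone features feed the head directly); used as the
#'   ablation arm in the shortcut experiment.
#' @param norm_mean,norm_sd channel normalization constants.
#' @param seed integer seed for parameter initialization.
#' @return a `stainmil_model` object.
#' @export
model_init <- function(side = 64L, backbone = NULL, sda_window = 7L,
                       head = head_config(), ablate_sda = FALSE,
                       norm_mean = c(0.5, 0.5, 0.5), norm_sd = c(0.5, 0.5, 0.5),
                       seed = 1L) {
  if (is.null(backbone)) backbone <- backbone_mini(seed = seed)
  C <- backbone$channels
  grid <- c(side %/% backbone$stride, side %/% backbone$stride)
  params <- list(backbone = backbone$params)
  if (!ablate_sda) params$sda <- sda_init(C, seed = seed + 1L)
  params$head <- head_init(C, head, grid_shape = grid, seed = seed + 2L)
  # geometry is fixed for a given input side: precompute it once
  coords <- grid_coords(grid[1], grid[2])
  static <- list(
    coords = coords,
    topo = build_topology(coords, head$r),
    Epe = if (head$pe == "sinusoidal") pe_sinusoidal(coords, head$d) else NULL,
    plan = if (!ablate_sda) window_plan(grid[1], grid[2], sda_window) else NULL
  )
  structure(list(
    params = params, backbone = backbone, head_config = head,
    side = as.integer(side), channels = C, ablate_sda = ablate_sda,
    sda_window = as.integer(sda_window), static = static,
    norm_mean = norm_mean, norm_sd = norm_sd
  ), class = "stainmil_model")
}

#' @export
print.stainmil_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, 1L))
  cat(sprintf(
    "stainmil model: side %d, backbone '%s' (stride %d, C=%d), %s, head d=%d L=%d r=%.2f, %d parameters\n",
    x$side, x$backbone$kind, x$backbone$stride, x$channels,
    if (x$ablate_sda) "SDA ablated" else "SDA enabled",
    x$head_config$d, x$head_config$L, x$head_config$r, np
  ))
  invisible(x)
}

#' Forward pass of the full model
#'
#' @param model a `stainmil_model`.
#' @param image a normalized image tensor (side x side x 3). Use
#'   [resize_and_normalize()] (or [prepare_inputs()]) first.
#' @return list(probs = length-2 vector (Normal, OSCC), logits, cache).
#' @export
model_forward <- function(model, image) {
  bb <- model$backbone$forward(model$params$backbone, image)
  tokens <- token_grid(bb$features, bb$grid)
  if (!identical(dim(model$static$coords), dim(tokens$coords)) ||
      !all(model$static$coords == tokens$coords)) {
    stop(sprintf("input yields a %d x %d token grid; model was built for %d x %d",
                 bb$grid[1], bb$grid[2], model$side %/% model$backbone$stride,
                 model$side %/% model$backbone$stride), call. = FALSE)
  }
  if (model$ablate_sda) {
    fused <- tokens$features
    sda_cache <- NULL
  } else {
    sf <- sda_forward(model$params$sda, tokens, model$sda_window, model$static$plan)
    fused <- sf$fused
    sda_cache <- sf$cache
  }
  hf <- head_forward(model$params$head, fused, tokens$coords, model$head_config,
                     static = model$static)
  list(probs = hf$probs, logits = hf$logits,
       cache = list(bb = bb, tokens = tokens, sda = sda_cache, head = hf$cache))
}

#' Class-weighted cross-entropy loss and gradients for one image
#'
#' @param model a `stainmil_model`.
#' @param image normalized image tensor.
#' @param y true label (0 Normal / 1 OSCC).
#' @param class_weight length-2 positive weights (Normal, OSCC).
#' @return list(loss, probs, grads) with `grads` shaped like `model$params`.
#' @export
model_loss_grad <- function(model, image, y, class_weight = c(1, 1)) {
  fw <- model_forward(model, image)
  y <- as_binary_label(y)
  w <- class_weight[y + 1L]
  p <- fw$probs
  loss <- -w * log(max(p[y + 1L], 1e-12))
  onehot <- c(0, 0); onehot[y + 1L] <- 1
  dlogits <- w * (p - onehot)           # softmax + CE gradient
  hb <- head_backward(model$params$head, fw$cache$head, dlogits)
  grads <- list(head = hb$grads)
  dFeat <- hb$dFused
  if (!model$ablate_sda) {
    sb <- sda_backward(model$params$sda, fw$cache$sda, dFeat)
    grads$sda <- sb$grads
    dFeat <- sb$dF
  }
  grads$backbone <- model$backbone$backward(model$params$backbone, fw$cache$bb$cache, dFeat)
  list(loss = loss, probs = fw$probs, grads = grads)
}

#' Predict OSCC probabilities for a set of images
#'
#' @param model a `stainmil_model`.
#' @param images list of normalized image tensors.
#' @return numeric vector of P(OSCC) per image.
#' @export
model_predict <- function(model, images) {
  vapply(images, function(img) model_forward(model, img)$probs[2L], numeric(1))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the parameter tree, configuration and optional metadata
#' (epoch, validation metrics, ablation flags).
#'
#' @param model a `stainmil_model`.
#' @param path destination file.
#' @param meta optional named list of metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(params = model$params,
              config = list(side = model$side, channels = model$channels,
                            ablate_sda = model$ablate_sda,
                            sda_window = model$sda_window,
                            head = model$head_config,
                            backbone_kind = model$backbone$kind,
                            norm_mean = model$norm_mean, norm_sd = model$norm_sd),
              meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param template optional model to restore parameters into; when NULL a
#'   fresh mini-backbone model matching the stored configuration is built.
#' @export
load_checkpoint <- function(path, template = NULL) {
  obj <- readRDS(path)
  cfg <- obj$config
  model <- template
  if (is.null(model)) {
    if (cfg$backbone_kind != "mini") {
      stop("checkpoint used a backbone adapter; pass a matching `template` model", call. = FALSE)
    }
    # mini-backbone geometry is recoverable from the stored weight shapes
    bp <- obj$params$backbone
    bb <- backbone_mini(channels = ncol(bp$W2), hidden = ncol(bp$W1),
                        patch = as.integer(round(sqrt(nrow(bp$W1) / 3))))
    model <- model_init(side = cfg$side, backbone = bb, head = cfg$head,
                        ablate_sda = cfg$ablate_sda,
                        sda_window = cfg$sda_window %||% 7L,
                        norm_mean = cfg$norm_mean, norm_sd = cfg$norm_sd)
  }
  model$params <- obj$params
  attr(model, "meta") <- obj$meta
  model
}
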