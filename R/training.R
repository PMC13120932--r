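# Training protocol: stratified 7:1:2 splitting, class-weighted cross-entropy
# with class-balanced batch sampling, AdamW with cosine annealing and global
# gradient-norm clipping, checkpoint selection on validation F1.

#' Stratified train/validation/test split
#'
#' Within each class, `round(0.7 n)` samples go to train, `round(0.1 n)` to
#' validation and the remainder to test (this rounding rule reproduces the
#' published per-class split counts of both benchmark datasets exactly).
#' Assignment is by a seeded within-class shuffle and is deterministic.
#'
#' @param labels binary label vector (0/1 or "Normal"/"OSCC").
#' @param ratios split ratios, must sum to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed integer seed.
#' @return character vector of "train"/"val"/"test" tags, one per sample.
#' @export
stratified_split <- function(labels, ratios = c(0.7, 0.1, 0.2), seed = 42L) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present to split", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1", call. = FALSE)
  out <- character(length(y))
  set.seed(seed)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n <- length(idx)
    if (n < 3L) stop(sprintf("class %d has only %d samples; need at least 3", cl, n), call. = FALSE)
    n_tr <- round(ratios[1] * n)
    n_va <- round(ratios[2] * n)
    if (n_tr + n_va >= n) stop(sprintf("class %d too small for the requested ratios", cl), call. = FALSE)
    idx <- sample(idx)
    out[idx[seq_len(n_tr)]] <- "train"
    out[idx[n_tr + seq_len(n_va)]] <- "val"
    out[idx[(n_tr + n_va + 1L):n]] <- "test"
  }
  out
}

#' Per-class split counts
#' @param labels binary labels; @param split split tags from [stratified_split()].
#' @return tibble with class, train, val, test counts.
#' @export
split_counts <- function(labels, split) {
  y <- as_binary_label(labels)
  tibble::tibble(
    class = c("Normal", "OSCC"),
    train = c(sum(y == 0 & split == "train"), sum(y == 1 & split == "train")),
    val   = c(sum(y == 0 & split == "val"),   sum(y == 1 & split == "val")),
    test  = c(sum(y == 0 & split == "test"),  sum(y == 1 & split == "test"))
  )
}

#' Balanced inverse-frequency class weights
#'
#' `w_c = n_train / (2 n_c)`: the minority class is up-weighted so both
#' classes contribute equally to the expected cross-entropy.
#'
#' @param train_labels binary labels of the training set.
#' @return length-2 numeric vector (Normal weight, OSCC weight).
#' @export
class_weights <- function(train_labels) {
  y <- as_binary_label(train_labels)
  n <- length(y)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present in the training set", call. = FALSE)
  c(n / (2 * n0), n / (2 * n1))
}

#' Cosine annealing learning rate
#'
#' `lr(t) = lr0 * (1 + cos(pi t / T)) / 2` for epoch t = 0 .. T-1; starts at
#' the initial rate and decays towards 0.
#'
#' @param lr0 initial learning rate.
#' @param epoch 0-based epoch index.
#' @param total total number of epochs.
#' @return learning rate for this epoch.
#' @export
cosine_lr <- function(lr0, epoch, total) {
  lr0 * (1 + cos(pi * epoch / total)) / 2
}

#' Clip a gradient tree to a maximum global L2 norm
#'
#' @param grads parameter-shaped gradient tree.
#' @param max_norm maximum global norm (default 1.0).
#' @return list(grads, norm) with the pre-clip global norm.
#' @export
clip_global_norm <- function(grads, max_norm = 1.0) {
  nrm <- sqrt(params_sumsq(grads))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- map_params(grads, function(g) g * (max_norm / nrm))
  }
  list(grads = grads, norm = nrm)
}

# One AdamW update. state carries first/second moments and step count;
# weight decay is decoupled (applied to the parameters, not the gradient).
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = zeros_like(params), v = zeros_like(params), t = 0L)
  }
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - lr * (u + weight_decay * p))
  list(params = params, state = state)
}

#' Default training configuration
#'
#' Mirrors the published training recipe: batch size 32, AdamW, initial
#' learning rate 1e-4, weight decay 1e-2, cosine annealing, gradient clipping
#' at global norm 1.0, seed 42. The desk-scale defaults here shorten the
#' schedule (`epochs`) and may raise the learning rate; both are plain
#' entries that callers can override.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param clip_norm global gradient-norm clip.
#' @param seed RNG seed for batch order and initialization.
#' @param balanced_batches if TRUE (default), training batches are drawn by
#'   stratified class-balanced sampling; otherwise plain shuffling.
#' @param select_metric validation metric for checkpoint selection
#'   ("f1" default, or "acc").
#' @return named list of training settings.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, lr = 1e-4,
                         weight_decay = 1e-2, clip_norm = 1.0, seed = 42L,
                         balanced_batches = TRUE, select_metric = c("f1", "acc")) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weight_decay = weight_decay, clip_norm = clip_norm,
       seed = as.integer(seed), balanced_batches = balanced_batches,
       select_metric = match.arg(select_metric))
}

# Class-balanced batch order: each epoch, oversample the minority class so
# every batch holds both classes in roughly equal proportion in expectation.
balanced_order <- function(y) {
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  n <- length(y)
  take <- function(idx, k) idx[1 + (seq_len(k) - 1L) %% length(idx)]
  pool <- c(take(sample(i0), ceiling(n / 2)), take(sample(i1), floor(n / 2)))
  sample(pool)
}

#' Train a model with class-weighted cross-entropy
#'
#' Runs AdamW with cosine-annealed learning rate and global-norm gradient
#' clipping over per-class-balanced minibatches, evaluates the validation
#' split after every epoch and returns the checkpoint with the best
#' validation metric (F1 by default).
#'
#' @param model a `stainmil_model`.
#' @param data list with `images` (list of normalized tensors), `labels`
#'   (binary vector) and `split` ("train"/"val"/... tags), e.g. from
#'   [prepare_inputs()].
#' @param config from [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return list(model = best checkpoint, history = per-epoch tibble,
#'   best_epoch).
#' @export
train_model <- function(model, data, config = train_config(), quiet = TRUE) {
  tr <- which(data$split == "train")
  va <- which(data$split == "val")
  if (length(va) == 0L) stop("validation split is empty", call. = FALSE)
  y <- as_binary_label(data$labels)
  cw <- class_weights(y[tr])
  set.seed(config$seed)
  params <- model$params
  state <- NULL
  history <- vector("list", config$epochs)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(config$lr, ep - 1L, config$epochs)
    order_idx <- if (config$balanced_batches) tr[balanced_order(y[tr])] else sample(tr)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    ep_loss <- 0; n_seen <- 0L
    for (b in batches) {
      gsum <- NULL
      bloss <- 0
      for (i in b) {
        model$params <- params
        lg <- model_loss_grad(model, data$images[[i]], y[i], cw)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite loss at epoch %d (sample %d); aborting", ep, i), call. = FALSE)
        }
        bloss <- bloss + lg$loss
        gsum <- if (is.null(gsum)) lg$grads else map2_params(gsum, lg$grads, `+`)
      }
      gmean <- map_params(gsum, function(g) g / length(b))
      clipped <- clip_global_norm(gmean, config$clip_norm)
      stepped <- adamw_step(params, clipped$grads, state, lr, config$weight_decay)
      params <- stepped$params
      state <- stepped$state
      ep_loss <- ep_loss + bloss
      n_seen <- n_seen + length(b)
    }
    model$params <- params
    val_scores <- model_predict(model, data$images[va])
    val_rep <- metric_report(y[va], val_scores)
    val_loss <- -mean(cw[y[va] + 1L] *
                      log(pmax(ifelse(y[va] == 1L, val_scores, 1 - val_scores), 1e-12)))
    metric <- val_rep[[config$select_metric]]
    if (is.na(metric)) metric <- -Inf
    history[[ep]] <- tibble::tibble(
      epoch = ep, lr = lr, train_loss = ep_loss / n_seen, val_loss = val_loss,
      val_acc = val_rep$acc, val_f1 = val_rep$f1, val_auc = val_rep$auc
    )
    if (metric > best$metric) best <- list(metric = metric, params = params, epoch = ep)
    if (!quiet) {
      message(sprintf("epoch %d: lr %.2e train loss %.4f val loss %.4f val acc %.2f val f1 %.2f",
                      ep, lr, ep_loss / n_seen, val_loss, val_rep$acc, val_rep$f1))
    }
  }
  model$params <- best$params
  list(model = model, history = do.call(rbind, history), best_epoch = best$epoch)
}

#' Prepare manifest images for the model
#'
#' Loads (or takes in-memory) images, resizes to the model input side and
#' applies channel normalization.
#'
#' @param manifest tibble with at least `path` (or an `images` list attached
#'   as an attribute / passed via `images`) and `label`, `split` columns.
#' @param model a `stainmil_model` (for side and normalization constants).
#' @param images optional list of raw H x W x 3 arrays overriding `path`.
#' @return list(images, labels, split) ready for [train_model()].
#' @export
prepare_inputs <- function(manifest, model, images = NULL) {
  raws <- if (!is.null(images)) images else lapply(manifest$path, load_image)
  normed <- lapply(raws, resize_and_normalize, side = model$side,
                   mean = model$norm_mean, sd = model$norm_sd)
  # patch extraction is input-only work: do it once, not once per epoch
  if (!is.null(model$backbone$prep)) normed <- lapply(normed, model$backbone$prep)
  list(images = normed, labels = manifest$label, split = manifest$split)
}
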