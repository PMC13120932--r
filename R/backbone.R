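# Token backbone: maps a normalized image tensor to a token-level feature
# matrix F (N x C) on a 2-D grid, plus the grid geometry. Tokens are ordered
# row-major; coordinates are 0-based (row, col) in token-grid units.

#' Construct a token grid
#'
#' @param features N x C numeric matrix of per-token features.
#' @param grid_shape integer vector `c(gh, gw)` with `gh * gw == N`.
#' @return a `stainmil_tokens` object: list with `features`, `grid_shape`,
#'   `coords` (N x 2 integer matrix, 0-based row-major (row, col)).
#' @export
token_grid <- function(features, grid_shape) {
  features <- as.matrix(features)
  gh <- as.integer(grid_shape[1]); gw <- as.integer(grid_shape[2])
  if (nrow(features) != gh * gw) {
    stop(sprintf("token count %d != grid %d x %d", nrow(features), gh, gw), call. = FALSE)
  }
  stopifnot_finite(features, "token features")
  structure(
    list(features = features, grid_shape = c(gh, gw), coords = grid_coords(gh, gw)),
    class = "stainmil_tokens"
  )
}

# 0-based row-major (row, col) coordinates for a gh x gw grid.
grid_coords <- function(gh, gw) {
  i <- seq_len(gh * gw) - 1L
  cbind(row = i %/% gw, col = i %% gw)
}

# ---- patch algebra ---------------------------------------------------------
# im2patch: (H, W, K) array -> (N x p*p*K) matrix, one row per non-overlapping
# p x p patch, rows ordered row-major over the patch grid. patch_rows_to_*
# invert it. These reshapes carry both the backbone forward pass and its
# gradient scatter.

im2patch <- function(a, p) {
  d <- dim(a); H <- d[1]; W <- d[2]; K <- d[3]
  gh <- H %/% p; gw <- W %/% p
  stopifnot(gh * p == H, gw * p == W)
  x <- array(a, c(p, gh, p, gw, K))          # [i, pr, j, pc, k]
  y <- aperm(x, c(4, 2, 1, 3, 5))            # [pc, pr, i, j, k]
  dim(y) <- c(gw * gh, p * p * K)            # row index = pc + gw*(pr-1): row-major
  list(x = y, grid = c(gh, gw))
}

patch2im <- function(X, p, gh, gw, K) {
  y <- array(X, c(gw, gh, p, p, K))
  x <- aperm(y, c(3, 2, 4, 1, 5))            # [i, pr, j, pc, k]
  array(x, c(gh * p, gw * p, K))
}

# row-major token rows <-> (gh, gw, K) grid array
rows_to_grid <- function(M, gh, gw) {
  K <- ncol(M)
  y <- array(M, c(gw, gh, K))
  aperm(y, c(2, 1, 3))
}

grid_to_rows <- function(G) {
  d <- dim(G)
  y <- aperm(G, c(2, 1, 3))
  dim(y) <- c(d[1] * d[2], d[3])
  y
}

# ---- mini backbone ---------------------------------------------------------

#' Trainable desk-scale token backbone
#'
#' A small two-stage patch-embedding backbone: a `patch x patch` linear patch
#' embedding with ReLU, followed by a 2x2 patch-merging linear projection.
#' Total downsampling stride is `patch * 2` (default 8), so a 64 x 64 input
#' yields an 8 x 8 token grid. It is deliberately tiny: spatial context is
#' the job of the downstream morphology branch and classifier head, and a
#' compact trainable backbone keeps end-to-end gradient computation fast on a
#' single CPU.
#'
#' @param channels output channel dimension C (default 24).
#' @param hidden stage-1 embedding width (default 16).
#' @param patch stage-1 patch side in pixels (default 4).
#' @param seed integer seed for weight initialization.
#' @return a backbone handle (list with `kind`, `stride`, `channels`,
#'   `params`, `forward`, `backward`).
#' @export
backbone_mini <- function(channels = 24L, hidden = 16L, patch = 4L, seed = 1L) {
  set.seed(seed)
  d1 <- patch * patch * 3L
  d2 <- 4L * hidden
  params <- list(
    W1 = init_mat(d1, hidden), b1 = numeric(hidden),
    W2 = init_mat(d2, channels), b2 = numeric(channels)
  )
  forward <- function(params, img) {
    pc1 <- if (inherits(img, "stainmil_patches")) img else im2patch(img, patch)
    Z1pre <- pc1$x %*% params$W1
    Z1pre <- Z1pre + rep(params$b1, each = nrow(Z1pre))
    Z1 <- relu(Z1pre)
    g1 <- rows_to_grid(Z1, pc1$grid[1], pc1$grid[2])
    pc2 <- im2patch(g1, 2L)
    FF <- pc2$x %*% params$W2
    FF <- FF + rep(params$b2, each = nrow(FF))
    list(features = FF, grid = pc2$grid,
         cache = list(X1 = pc1$x, Z1pre = Z1pre, X2 = pc2$x, g1dim = dim(g1)))
  }
  backward <- function(params, cache, dF) {
    dW2 <- crossprod(cache$X2, dF)
    db2 <- colSums(dF)
    dX2 <- dF %*% t(params$W2)
    gh1 <- cache$g1dim[1]; gw1 <- cache$g1dim[2]; K1 <- cache$g1dim[3]
    dg1 <- patch2im(dX2, 2L, gh1 %/% 2L, gw1 %/% 2L, K1)
    dZ1 <- grid_to_rows(dg1) * (cache$Z1pre > 0)
    list(W1 = crossprod(cache$X1, dZ1), b1 = colSums(dZ1), W2 = dW2, b2 = db2)
  }
  prep <- function(img) structure(im2patch(img, patch), class = "stainmil_patches")
  structure(list(kind = "mini", stride = patch * 2L, channels = channels,
                 params = params, forward = forward, backward = backward,
                 prep = prep),
            class = "stainmil_backbone")
}

#' Wrap an external feature extractor as a backbone adapter
#'
#' Adapter slot for hierarchical (Swin-style) backbones: any function mapping
#' a normalized image tensor to final-stage token features can be plugged in.
#' Adapters are treated as frozen (no gradients are propagated into them).
#'
#' @param forward_fn function(img) returning an N x C feature matrix, tokens
#'   ordered row-major over the grid.
#' @param stride total downsampling factor of the wrapped backbone.
#' @param channels output channel dimension C.
#' @return a backbone handle.
#' @export
backbone_adapter <- function(forward_fn, stride, channels) {
  forward <- function(params, img) {
    d <- dim(img)
    grid <- c(d[1] %/% stride, d[2] %/% stride)
    FF <- as.matrix(forward_fn(img))
    if (nrow(FF) != prod(grid) || ncol(FF) != channels) {
      stop(sprintf("adapter returned %d x %d features; expected %d x %d",
                   nrow(FF), ncol(FF), prod(grid), channels), call. = FALSE)
    }
    list(features = FF, grid = grid, cache = NULL)
  }
  structure(list(kind = "adapter", stride = as.integer(stride),
                 channels = as.integer(channels), params = list(),
                 forward = forward, backward = function(params, cache, dF) list()),
            class = "stainmil_backbone")
}

#' Extract a token grid from an image with a backbone
#'
#' @param image a normalized image tensor (H x W x 3 array).
#' @param backbone a backbone handle from [backbone_mini()] or
#'   [backbone_adapter()].
#' @return a `stainmil_tokens` object whose grid shape is the image size
#'   divided by the backbone stride.
#' @export
extract_tokens <- function(image, backbone) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("non-RGB input: expected an H x W x 3 array", call. = FALSE)
  }
  s <- backbone$stride
  if (d[1] < s || d[2] < s) {
    stop(sprintf("image %d x %d smaller than one backbone patch (stride %d)",
                 d[1], d[2], s), call. = FALSE)
  }
  if (d[1] %% s != 0 || d[2] %% s != 0) {
    stop(sprintf("image size %d x %d not divisible by backbone stride %d",
                 d[1], d[2], s), call. = FALSE)
  }
  out <- backbone$forward(backbone$params, image)
  token_grid(out$features, out$grid)
}
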