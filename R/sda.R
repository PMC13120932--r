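# Morphology-dominant encoding with staining-bias suppression.
#
# Backbone tokens F (N x C) are factorized into a stain-related component
# Fs = MLP_s(F) (token-local) and a morphology-dominant component
# Fm = F + DWConv(WAttn(F)) (residual over windowed attention plus a 3x3
# depthwise convolution on the token grid). A per-token sigmoid gate
# alpha = sigmoid(F w_a + b_a) interpolates them:
#   F~ = alpha (.) Fm + (1 - alpha) (.) Fs
# with alpha broadcast across channels. The decomposition is architectural;
# it is trained end-to-end by the classification loss alone.

#' Initialize stain-suppression module parameters
#'
#' @param channels token channel dimension C.
#' @param seed integer seed.
#' @return parameter list (stain-branch MLP, morph-branch attention +
#'   depthwise kernel, gate weights). The attention window size is
#'   configuration, not a parameter; it is passed to [sda_forward()].
#' @export
sda_init <- function(channels, seed = 1L) {
  set.seed(seed)
  C <- as.integer(channels)
  list(
    Ws1 = init_mat(C, C), bs1 = numeric(C),
    Ws2 = init_mat(C, C), bs2 = numeric(C),
    Wq = init_mat(C, C), Wk = init_mat(C, C), Wv = init_mat(C, C),
    Kdw = array(stats::rnorm(9 * C, sd = 0.05), c(3, 3, C)),
    walpha = numeric(C), balpha = 0
  )
}

# ---- window geometry -------------------------------------------------------
# Non-overlapping windows of side w over a gh x gw grid. Grids not divisible
# by w are padded by edge replication (clamped coordinates); each padded cell
# maps to a source token, and each source token is "primary" in exactly one
# cell. A grid smaller than one window falls back to a single global window.

window_plan <- function(gh, gw, w) {
  if (gh < w || gw < w) {
    message(sprintf("token grid %d x %d smaller than attention window %d; using one global window", gh, gw, w))
    return(list(list(src = seq_len(gh * gw), primary = rep(TRUE, gh * gw))))
  }
  nwh <- ceiling(gh / w); nwv <- ceiling(gw / w)
  plan <- list()
  for (br in seq_len(nwh) - 1L) {
    for (bc in seq_len(nwv) - 1L) {
      rows <- br * w + seq_len(w) - 1L
      cols <- bc * w + seq_len(w) - 1L
      rr <- pmin(rows, gh - 1L)  # edge replication
      cc <- pmin(cols, gw - 1L)
      cells <- expand.grid(col = cc, row = rr, KEEP.OUT.ATTRS = FALSE)
      pads <- expand.grid(col = cols, row = rows, KEEP.OUT.ATTRS = FALSE)
      src <- cells$row * gw + cells$col + 1L
      primary <- cells$row == pads$row & cells$col == pads$col
      plan[[length(plan) + 1L]] <- list(src = src, primary = primary)
    }
  }
  plan
}

# ---- branches --------------------------------------------------------------

#' Stain-related branch: per-token feed-forward map
#'
#' A lightweight token-wise MLP (one hidden layer of width C, ReLU); no
#' cross-token mixing, so it can model color distribution and staining
#' intensity but not spatial structure.
#'
#' @param params SDA parameter list from [sda_init()].
#' @param F N x C token feature matrix.
#' @return list(Fs, cache).
#' @export
stain_branch <- function(params, F) {
  H1pre <- sweep(F %*% params$Ws1, 2, params$bs1, "+")
  H1 <- relu(H1pre)
  Fs <- sweep(H1 %*% params$Ws2, 2, params$bs2, "+")
  list(Fs = Fs, cache = list(F = F, H1pre = H1pre, H1 = H1))
}

stain_branch_backward <- function(params, cache, dFs) {
  dWs2 <- crossprod(cache$H1, dFs)
  dbs2 <- colSums(dFs)
  dH1 <- dFs %*% t(params$Ws2)
  dH1pre <- dH1 * (cache$H1pre > 0)
  list(
    grads = list(Ws1 = crossprod(cache$F, dH1pre), bs1 = colSums(dH1pre),
                 Ws2 = dWs2, bs2 = dbs2),
    dF = dH1pre %*% t(params$Ws1)
  )
}

#' Morphology-dominant branch: residual windowed attention + depthwise conv
#'
#' `Fm = F + DWConv(WAttn(F))`: single-head scaled dot-product attention in
#' non-overlapping windows on the token grid, followed by a 3x3 depthwise
#' convolution (zero padding), added back to the input. With all branch
#' parameters zero the branch is the identity.
#'
#' @param params SDA parameter list.
#' @param F N x C token feature matrix.
#' @param grid integer `c(gh, gw)`.
#' @param window attention window side in tokens (default 7).
#' @return list(Fm, cache).
#' @export
morph_branch <- function(params, F, grid, window = 7L, plan = NULL) {
  C <- ncol(F)
  plan <- plan %||% window_plan(grid[1], grid[2], window)
  U <- matrix(0, nrow(F), C)
  wcache <- vector("list", length(plan))
  for (wi in seq_along(plan)) {
    p <- plan[[wi]]
    Fw <- F[p$src, , drop = FALSE]
    Q <- Fw %*% params$Wq; K <- Fw %*% params$Wk; V <- Fw %*% params$Wv
    A <- softmax_rows(Q %*% t(K) / sqrt(C))
    Uw <- A %*% V
    U[p$src[p$primary], ] <- Uw[p$primary, , drop = FALSE]
    wcache[[wi]] <- list(Fw = Fw, Q = Q, K = K, V = V, A = A)
  }
  Ug <- rows_to_grid(U, grid[1], grid[2])
  Dg <- dwconv_forward(Ug, params$Kdw)
  D <- grid_to_rows(Dg)
  list(Fm = F + D, cache = list(plan = plan, wcache = wcache, U = U, Ug = Ug, grid = grid))
}

morph_branch_backward <- function(params, cache, dFm) {
  C <- ncol(dFm)
  grid <- cache$grid
  # residual: dF gets dFm directly; conv path:
  dDg <- rows_to_grid(dFm, grid[1], grid[2])
  conv_bwd <- dwconv_backward(cache$Ug, params$Kdw, dDg)
  dU <- grid_to_rows(conv_bwd$dX)
  dF <- dFm  # residual term
  dWq <- matrix(0, C, C); dWk <- matrix(0, C, C); dWv <- matrix(0, C, C)
  for (wi in seq_along(cache$plan)) {
    p <- cache$plan[[wi]]
    cw <- cache$wcache[[wi]]
    dUw <- matrix(0, length(p$src), C)
    dUw[p$primary, ] <- dU[p$src[p$primary], , drop = FALSE]
    dV <- crossprod(cw$A, dUw)
    dA <- dUw %*% t(cw$V)
    dS <- cw$A * (dA - rowSums(dA * cw$A))
    dQ <- dS %*% cw$K / sqrt(C)
    dK <- crossprod(dS, cw$Q) / sqrt(C)
    dWq <- dWq + crossprod(cw$Fw, dQ)
    dWk <- dWk + crossprod(cw$Fw, dK)
    dWv <- dWv + crossprod(cw$Fw, dV)
    dFw <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
    # scatter-add over (possibly duplicated) source tokens
    agg <- rowsum(dFw, p$src)
    rows <- as.integer(rownames(agg))
    dF[rows, ] <- dF[rows, ] + agg
  }
  list(grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Kdw = conv_bwd$dK), dF = dF)
}

# 3x3 depthwise convolution on a (gh, gw, C) grid with zero padding.
dwconv_forward <- function(X, K) {
  d <- dim(X); gh <- d[1]; gw <- d[2]; C <- d[3]
  out <- array(0, d)
  for (u in -1:1) for (v in -1:1) {
    ri <- max(1, 1 + u):min(gh, gh + u)   # output rows receiving X[r - u]
    ci <- max(1, 1 + v):min(gw, gw + v)
    kw <- rep(K[u + 2, v + 2, ], each = length(ri) * length(ci))
    out[ri, ci, ] <- out[ri, ci, , drop = FALSE] +
      X[ri - u, ci - v, , drop = FALSE] * kw
  }
  out
}

dwconv_backward <- function(X, K, dOut) {
  d <- dim(X); gh <- d[1]; gw <- d[2]; C <- d[3]
  dX <- array(0, d)
  dK <- array(0, dim(K))
  for (u in -1:1) for (v in -1:1) {
    ri <- max(1, 1 + u):min(gh, gh + u)
    ci <- max(1, 1 + v):min(gw, gw + v)
    kw <- rep(K[u + 2, v + 2, ], each = length(ri) * length(ci))
    xs <- X[ri - u, ci - v, , drop = FALSE]
    ds <- dOut[ri, ci, , drop = FALSE]
    dK[u + 2, v + 2, ] <- colSums(matrix(xs * ds, ncol = C))
    dX[ri - u, ci - v, ] <- dX[ri - u, ci - v, , drop = FALSE] + ds * kw
  }
  list(dX = dX, dK = dK)
}

#' Token-level gate from raw backbone features
#'
#' `alpha = sigmoid(F w_a + b_a)`, one scalar per token in (0, 1), computed
#' from the raw backbone features (not from either branch output).
#'
#' @param params SDA parameter list.
#' @param F N x C raw token feature matrix.
#' @return list(alpha = N-vector, cache).
#' @export
sda_gate <- function(params, F) {
  pre <- drop(F %*% params$walpha) + params$balpha
  list(alpha = sigmoid(pre), cache = list(F = F))
}

#' Gated fusion of morphology and stain components
#'
#' Rowwise convex combination `F~_i = alpha_i Fm_i + (1 - alpha_i) Fs_i`.
#'
#' @param Fm,Fs N x C matrices.
#' @param alpha length-N gate vector in (0, 1).
#' @return N x C fused feature matrix.
#' @export
sda_fuse <- function(Fm, Fs, alpha) {
  if (!all(dim(Fm) == dim(Fs)) || length(alpha) != nrow(Fm)) {
    stop("shape mismatch in gated fusion", call. = FALSE)
  }
  Fm * alpha + Fs * (1 - alpha)
}

#' Full stain-suppression forward pass
#'
#' @param params SDA parameter list from [sda_init()].
#' @param tokens a `stainmil_tokens` object.
#' @param window attention window side in tokens (default 7).
#' @return list(fused = N x C matrix, alpha, cache).
#' @export
sda_forward <- function(params, tokens, window = 7L, plan = NULL) {
  F <- tokens$features
  sb <- stain_branch(params, F)
  mb <- morph_branch(params, F, tokens$grid_shape, window, plan)
  g <- sda_gate(params, F)
  fused <- sda_fuse(mb$Fm, sb$Fs, g$alpha)
  list(fused = fused, alpha = g$alpha,
       cache = list(F = F, sb = sb, mb = mb, alpha = g$alpha))
}

sda_backward <- function(params, cache, dFused) {
  alpha <- cache$alpha
  Fm <- cache$mb$Fm; Fs <- cache$sb$Fs
  dFm <- dFused * alpha
  dFs <- dFused * (1 - alpha)
  dalpha <- rowSums(dFused * (Fm - Fs))
  dpre <- dalpha * alpha * (1 - alpha)
  sbb <- stain_branch_backward(params, cache$sb$cache, dFs)
  mbb <- morph_branch_backward(params, cache$mb$cache, dFm)
  dF <- sbb$dF + mbb$dF + outer(dpre, params$walpha)
  grads <- c(sbb$grads, mbb$grads,
             list(walpha = drop(crossprod(cache$F, dpre)), balpha = sum(dpre)))
  list(grads = grads, dF = dF)
}
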