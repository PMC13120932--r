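# Spatial Transformer Classifier Head.
#
# Tokens become graph nodes carrying a geometric embedding of their grid
# coordinates. A radius-r Euclidean neighborhood splits node pairs into
# adjacent and non-adjacent sets; content similarity scores from the initial
# node states are softmax-normalized within each set and fused by a learnable
# coefficient lambda into a single structure matrix A^, computed once and
# reused by every layer. Each layer combines graph-transformer attention
# (fresh per-layer softmax multiplied elementwise by A^) with a dynamic graph
# convolution and residual. A tanh-bottleneck attention readout pools node
# states into an image-level vector, classified by a 2-way softmax.

#' Default head configuration
#'
#' @param d node state dimension (default 128).
#' @param r neighborhood radius in token-grid units (default 1.5, i.e. the
#'   8-neighborhood including diagonals).
#' @param L number of layers (default 2).
#' @param pe positional encoding mode, "sinusoidal" (deterministic,
#'   parameter-free before the projection) or "learnable".
#' @param renormalize_attention if TRUE, rows of the elementwise product of A^ and
#'   the per-layer attention are renormalized to sum to one; default FALSE
#'   (the literal product).
#' @return a named list of head settings.
#' @export
head_config <- function(d = 128L, r = 1.5, L = 2L, pe = c("sinusoidal", "learnable"),
                        renormalize_attention = FALSE) {
  pe <- match.arg(pe)
  if (L < 1L) stop("head depth L must be >= 1", call. = FALSE)
  if (r <= 0) stop("neighborhood radius r must be positive", call. = FALSE)
  list(d = as.integer(d), r = r, L = as.integer(L), pe = pe,
       renormalize_attention = renormalize_attention)
}

#' Initialize head parameters
#'
#' @param channels input token channel dimension C.
#' @param config from [head_config()].
#' @param grid_shape token grid `c(gh, gw)`; required for learnable positional
#'   encoding, otherwise optional.
#' @param seed integer seed.
#' @return parameter list.
#' @export
head_init <- function(channels, config = head_config(), grid_shape = NULL, seed = 1L) {
  set.seed(seed)
  d <- config$d
  p <- list(
    Wp = init_mat(d, d),
    Wf = init_mat(channels, d),
    Wq0 = init_mat(d, d), Wk0 = init_mat(d, d),
    theta_lambda = 0,                      # lambda = sigmoid(0) = 0.5
    layers = lapply(seq_len(config$L), function(l) list(
      Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
      Wg = init_mat(d, d)
    )),
    Wa = init_mat(d, d), u = stats::rnorm(d, sd = 0.1),
    Wc = init_mat(d, 2L), bc = numeric(2L)
  )
  if (config$pe == "learnable") {
    if (is.null(grid_shape)) stop("learnable positional encoding needs grid_shape", call. = FALSE)
    p$pe_table <- init_mat(prod(grid_shape), d, scale = 0.1)
  }
  p
}

# ---- positional encoding ---------------------------------------------------

# Fixed 2-D sinusoidal encoding: half the dimensions encode the row, half the
# column, as interleaved (sin, cos) pairs with geometric frequencies. At
# coordinate 0 all sine components are 0 and all cosine components 1.
pe_sinusoidal <- function(coords, d) {
  half <- d %/% 2L
  npair <- half %/% 2L
  if (npair < 1L) stop("positional encoding dimension too small", call. = FALSE)
  freq <- 1 / (10000^((seq_len(npair) - 1L) / npair))
  enc1 <- function(pos) {
    ang <- outer(pos, freq)                        # N x npair
    out <- matrix(0, length(pos), 2L * npair)
    out[, seq(1L, 2L * npair, by = 2L)] <- sin(ang)
    out[, seq(2L, 2L * npair, by = 2L)] <- cos(ang)
    out
  }
  E <- cbind(enc1(coords[, 1]), enc1(coords[, 2]))
  if (ncol(E) < d) E <- cbind(E, matrix(0, nrow(E), d - ncol(E)))
  E
}

#' Geometric embedding of token coordinates
#'
#' `e_i = PE(p_i) W_p`: a (sinusoidal or learnable) positional encoding of
#' the 0-based grid coordinates, linearly projected to the node dimension.
#'
#' @param params head parameter list.
#' @param coords N x 2 integer matrix of (row, col) grid coordinates.
#' @param config head configuration.
#' @return list(e = N x d matrix, Epe = pre-projection encoding).
#' @export
embed_positions <- function(params, coords, config) {
  idx <- NULL
  Epe <- switch(config$pe,
    sinusoidal = pe_sinusoidal(coords, nrow(params$Wp)),
    learnable = {
      gw <- max(coords[, 2]) + 1L
      idx <- coords[, 1] * gw + coords[, 2] + 1L
      params$pe_table[idx, , drop = FALSE]
    },
    stop(sprintf("unknown positional encoding mode '%s'", config$pe), call. = FALSE)
  )
  list(e = Epe %*% params$Wp, Epe = Epe, idx = idx)
}

#' Initial node states
#'
#' `h_i^(0) = f~_i W_f + e_i`.
#'
#' @param fused N x C fused feature matrix.
#' @param e N x d geometric embeddings.
#' @param Wf C x d feature projection.
#' @return N x d matrix of initial node states.
#' @export
init_nodes <- function(fused, e, Wf) {
  if (nrow(fused) != nrow(e)) stop("row count mismatch between features and embeddings", call. = FALSE)
  fused %*% Wf + e
}

# ---- topology and dynamic structure ---------------------------------------

#' Radius-based dual topology on the token grid
#'
#' Euclidean distances between grid coordinates; `A_adj[i, j] = 1` iff
#' `d_ij <= r` (the diagonal is always adjacent since `d_ii = 0`), and
#' `A_non = 1 - A_adj`.
#'
#' @param coords N x 2 integer coordinate matrix.
#' @param r neighborhood radius (> 0), token-grid units.
#' @return list(dist, adj, non) of N x N matrices.
#' @export
build_topology <- function(coords, r) {
  if (r <= 0) stop("radius must be positive", call. = FALSE)
  dr <- outer(coords[, 1], coords[, 1], "-")
  dc <- outer(coords[, 2], coords[, 2], "-")
  dist <- sqrt(dr^2 + dc^2)
  adj <- (dist <= r) * 1
  list(dist = dist, adj = adj, non = 1 - adj)
}

#' Content similarity scores between initial node states
#'
#' `S = (h0 Wq)(h0 Wk)^T / sqrt(d)`.
#'
#' @param h0 N x d initial node states.
#' @param Wq,Wk d x d projections.
#' @return N x N score matrix.
#' @export
similarity_scores <- function(h0, Wq, Wk) {
  d <- ncol(h0)
  (h0 %*% Wq) %*% t(h0 %*% Wk) / sqrt(d)
}

#' Masked softmax normalization over adjacent / non-adjacent supports
#'
#' Rowwise softmax of `S` restricted to each mask's support, stabilized by
#' max-subtraction per row support. Rows with empty support are all zero
#' (never NaN), the only finite order-independent convention.
#'
#' @param S N x N score matrix.
#' @param mask N x N binary support mask.
#' @return N x N row-stochastic (over nonempty supports) matrix.
#' @export
masked_softmax <- function(S, mask) {
  Sm <- S
  Sm[mask == 0] <- -Inf
  m <- Sm[cbind(seq_len(nrow(Sm)), max.col(Sm, ties.method = "first"))]
  ok <- which(is.finite(m))               # rows with nonempty support
  E <- matrix(0, nrow(S), ncol(S))
  if (length(ok)) {
    Es <- exp(Sm[ok, , drop = FALSE] - m[ok])   # exp(-Inf) = 0 off support
    E[ok, ] <- Es / rowSums(Es)
  }
  E
}

# gradient of masked softmax: dS = A * (dA - rowSums(dA * A)) on the support
masked_softmax_backward <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

#' Fuse adjacent and non-adjacent dynamic weights
#'
#' `A^ = lambda A^_adj + (1 - lambda) A^_non` with `lambda = sigmoid(theta)`
#' so the fusion coefficient stays in \[0, 1\] under gradient training.
#'
#' @param A_adj,A_non normalized dynamic adjacency matrices.
#' @param lambda scalar in \[0, 1\].
#' @return N x N fused structure matrix.
#' @export
fuse_structure <- function(A_adj, A_non, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  lambda * A_adj + (1 - lambda) * A_non
}

# ---- layers ----------------------------------------------------------------

#' One graph-transformer attention update
#'
#' `h^(l+1/2) = (A^ (.) softmax(Q K^T / sqrt(d))) (h^(l) Wv)`: a fresh
#' full softmax attention per layer, multiplied elementwise by the fixed
#' structure matrix. By default the product is used literally (rows need not
#' sum to one); `renormalize` restores row-stochasticity.
#'
#' @param h N x d node states.
#' @param Ahat N x N structure matrix.
#' @param lp layer parameter list (Wq, Wk, Wv).
#' @param renormalize logical.
#' @return list(h_half, cache).
#' @export
graph_attention_layer <- function(h, Ahat, lp, renormalize = FALSE) {
  d <- ncol(h)
  Q <- h %*% lp$Wq; K <- h %*% lp$Wk; V <- h %*% lp$Wv
  P <- softmax_rows(Q %*% t(K) / sqrt(d))
  Mraw <- Ahat * P
  if (renormalize) {
    rs <- rowSums(Mraw)
    rs_safe <- ifelse(rs > 0, rs, 1)
    M <- Mraw / rs_safe
  } else {
    rs_safe <- NULL
    M <- Mraw
  }
  list(h_half = M %*% V,
       cache = list(h = h, Q = Q, K = K, V = V, P = P, Mraw = Mraw, M = M,
                    rs_safe = rs_safe, renormalize = renormalize))
}

#' Dynamic graph convolution with residual
#'
#' `h^(l+1) = relu(A^ h^(l+1/2) Wg) + h^(l)`: the nonlinearity applies to the
#' aggregated term only; the residual adds the pre-attention state.
#'
#' @param h_half N x d intermediate states.
#' @param h_prev N x d pre-attention states.
#' @param Ahat N x N structure matrix.
#' @param Wg d x d graph-convolution weight.
#' @return list(h_next, cache).
#' @export
dynamic_graph_conv <- function(h_half, h_prev, Ahat, Wg) {
  B <- Ahat %*% h_half
  Gpre <- B %*% Wg
  list(h_next = relu(Gpre) + h_prev,
       cache = list(B = B, Gpre = Gpre, h_half = h_half))
}

#' Attention readout
#'
#' Gated-attention MIL pooling: `a_i = softmax_i(u^T tanh(h_i Wa))`,
#' `z = sum_i a_i h_i`; `z` lies in the convex hull of the node states.
#'
#' @param hL N x d final node states.
#' @param Wa d x d bottleneck projection.
#' @param u length-d scoring vector.
#' @return list(a = weights, z = pooled vector, cache).
#' @export
readout <- function(hL, Wa, u) {
  Tt <- tanh(hL %*% Wa)
  s <- drop(Tt %*% u)
  a <- softmax_vec(s)
  z <- drop(crossprod(hL, a))
  list(a = a, z = z, cache = list(Tt = Tt, s = s))
}

#' Two-class softmax classification
#'
#' @param z length-d pooled representation.
#' @param Wc d x 2 classifier weight.
#' @param bc length-2 bias.
#' @return list(probs = length-2 simplex vector, logits).
#' @export
classify <- function(z, Wc, bc) {
  logits <- drop(z %*% Wc) + bc
  list(probs = softmax_vec(logits), logits = logits)
}

# ---- full head -------------------------------------------------------------

#' Head forward pass
#'
#' Composition: positional embedding, node initialization, radius topology,
#' structure estimation (once, from h^(0)), L x (graph attention + dynamic
#' graph convolution), attention readout, softmax classifier.
#'
#' @param params head parameters from [head_init()].
#' @param fused N x C fused token features.
#' @param coords N x 2 grid coordinates.
#' @param config from [head_config()].
#' @param static optional precomputed geometry (list with `Epe` and `topo`)
#'   reused across calls on a fixed grid.
#' @return list(probs, logits, Ahat, a, cache).
#' @export
head_forward <- function(params, fused, coords, config = head_config(), static = NULL) {
  if (!is.null(static$Epe) && config$pe == "sinusoidal") {
    emb <- list(e = static$Epe %*% params$Wp, Epe = static$Epe, idx = NULL)
  } else {
    emb <- embed_positions(params, coords, config)
  }
  h0 <- init_nodes(fused, emb$e, params$Wf)
  topo <- static$topo %||% build_topology(coords, config$r)
  S <- similarity_scores(h0, params$Wq0, params$Wk0)
  A_adj <- masked_softmax(S, topo$adj)
  A_non <- masked_softmax(S, topo$non)
  lambda <- sigmoid(params$theta_lambda)
  Ahat <- fuse_structure(A_adj, A_non, lambda)
  h <- h0
  lcaches <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    att <- graph_attention_layer(h, Ahat, params$layers[[l]], config$renormalize_attention)
    conv <- dynamic_graph_conv(att$h_half, h, Ahat, params$layers[[l]]$Wg)
    lcaches[[l]] <- list(att = att$cache, conv = conv$cache)
    h <- conv$h_next
  }
  ro <- readout(h, params$Wa, params$u)
  cl <- classify(ro$z, params$Wc, params$bc)
  list(
    probs = cl$probs, logits = cl$logits, Ahat = Ahat, a = ro$a,
    cache = list(emb = emb, fused = fused, h0 = h0, topo = topo, S = S,
                 A_adj = A_adj, A_non = A_non, lambda = lambda, Ahat = Ahat,
                 lcaches = lcaches, hL = h, ro = ro, z = ro$z, config = config)
  )
}

# Backward pass from d(logits); returns parameter gradients and d(fused).
head_backward <- function(params, cache, dlogits) {
  config <- cache$config
  d <- ncol(cache$h0)
  # classifier
  dWc <- outer(cache$z, dlogits)
  dbc <- dlogits
  dz <- drop(params$Wc %*% dlogits)
  # readout
  ro <- cache$ro; hL <- cache$hL
  a <- ro$a; Tt <- ro$cache$Tt
  dhL <- outer(a, dz)
  da <- drop(hL %*% dz)
  ds <- a * (da - sum(da * a))
  dTt <- outer(ds, params$u)
  du <- drop(crossprod(Tt, ds))
  dpre <- dTt * (1 - Tt^2)
  dWa <- crossprod(hL, dpre)
  dhL <- dhL + dpre %*% t(params$Wa)
  # layers (reverse)
  dAhat <- matrix(0, nrow(cache$Ahat), ncol(cache$Ahat))
  dh <- dhL
  lgrads <- vector("list", config$L)
  for (l in rev(seq_len(config$L))) {
    lp <- params$layers[[l]]
    lc <- cache$lcaches[[l]]
    att <- lc$att; conv <- lc$conv
    dh_next <- dh
    dh_in <- dh_next                       # residual
    dGpre <- dh_next * (conv$Gpre > 0)
    dWg <- crossprod(conv$B, dGpre)
    dB <- dGpre %*% t(lp$Wg)
    dAhat <- dAhat + dB %*% t(conv$h_half)
    dh_half <- crossprod(cache$Ahat, dB)
    # attention
    dM <- dh_half %*% t(att$V)
    dV <- crossprod(att$M, dh_half)
    if (att$renormalize) {
      # M = Mraw / rowSums(Mraw): dMraw = (dM - rowSums(dM * M)) / rs
      rs <- att$rs_safe
      dMraw <- (dM - rowSums(dM * att$M)) / rs
      zero_rows <- rowSums(att$Mraw) == 0
      if (any(zero_rows)) dMraw[zero_rows, ] <- dM[zero_rows, , drop = FALSE]
    } else {
      dMraw <- dM
    }
    dAhat <- dAhat + dMraw * att$P
    dP <- dMraw * cache$Ahat
    dS_l <- att$P * (dP - rowSums(dP * att$P))
    dQ <- dS_l %*% att$K / sqrt(d)
    dK <- crossprod(dS_l, att$Q) / sqrt(d)
    dh_in <- dh_in + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    lgrads[[l]] <- list(Wq = crossprod(att$h, dQ), Wk = crossprod(att$h, dK),
                        Wv = crossprod(att$h, dV), Wg = dWg)
    dh <- dh_in
  }
  dh0 <- dh
  # structure estimation backward
  lambda <- cache$lambda
  dlambda <- sum(dAhat * (cache$A_adj - cache$A_non))
  dtheta <- dlambda * lambda * (1 - lambda)
  dA_adj <- lambda * dAhat
  dA_non <- (1 - lambda) * dAhat
  dS <- masked_softmax_backward(cache$A_adj, dA_adj) +
        masked_softmax_backward(cache$A_non, dA_non)
  Q0 <- cache$h0 %*% params$Wq0
  K0 <- cache$h0 %*% params$Wk0
  dQ0 <- dS %*% K0 / sqrt(d)
  dK0 <- crossprod(dS, Q0) / sqrt(d)
  dWq0 <- crossprod(cache$h0, dQ0)
  dWk0 <- crossprod(cache$h0, dK0)
  dh0 <- dh0 + dQ0 %*% t(params$Wq0) + dK0 %*% t(params$Wk0)
  # node init backward
  dWf <- crossprod(cache$fused, dh0)
  dFused <- dh0 %*% t(params$Wf)
  de <- dh0
  dWp <- crossprod(cache$emb$Epe, de)
  grads <- list(Wp = dWp, Wf = dWf, Wq0 = dWq0, Wk0 = dWk0,
                theta_lambda = dtheta, layers = lgrads,
                Wa = dWa, u = du, Wc = dWc, bc = dbc)
  if (config$pe == "learnable") {
    dE <- de %*% t(params$Wp)
    idx <- cache$emb$idx
    dtab <- matrix(0, nrow(params$pe_table), ncol(params$pe_table))
    for (i in seq_along(idx)) dtab[idx[i], ] <- dtab[idx[i], ] + dE[i, ]
    grads$pe_table <- dtab
  }
  list(grads = grads, dFused = dFused)
}
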