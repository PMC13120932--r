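# Scalar-loop reference implementations of the head equations, written
# directly from their definitions and kept independent of the vectorized
# package code: every sum is an explicit loop over indices.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# masked softmax, one row at a time, explicit exp/sum over the support
oracle_masked_softmax <- function(S, mask) {
  n <- nrow(S)
  out <- matrix(0, n, n)
  for (i in 1:n) {
    sup <- which(mask[i, ] > 0)
    if (length(sup) == 0) next
    e <- exp(S[i, sup] - max(S[i, sup]))
    out[i, sup] <- e / sum(e)
  }
  out
}

# similarity scores S_ij = (h_i Wq) . (h_j Wk) / sqrt(d), triple loop
oracle_similarity <- function(h0, Wq, Wk) {
  n <- nrow(h0); d <- ncol(h0)
  Q <- matrix(0, n, d); K <- matrix(0, n, d)
  for (i in 1:n) for (a in 1:d) {
    Q[i, a] <- sum(h0[i, ] * Wq[, a])
    K[i, a] <- sum(h0[i, ] * Wk[, a])
  }
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
  S
}

# one graph-transformer attention update, per-node loops
oracle_attention_layer <- function(h, Ahat, Wq, Wk, Wv) {
  n <- nrow(h); d <- ncol(h)
  Q <- h %*% Wq; K <- h %*% Wk; V <- h %*% Wv
  out <- matrix(0, n, d)
  for (i in 1:n) {
    sc <- numeric(n)
    for (j in 1:n) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    sm <- exp(sc - max(sc)); sm <- sm / sum(sm)
    for (j in 1:n) out[i, ] <- out[i, ] + Ahat[i, j] * sm[j] * V[j, ]
  }
  out
}

# dynamic graph convolution h^(l+1)_i = relu(sum_j A_ij h_half_j Wg) + h_i
oracle_graph_conv <- function(h_half, h_prev, Ahat, Wg) {
  n <- nrow(h_half); d <- ncol(h_half)
  out <- matrix(0, n, d)
  for (i in 1:n) {
    acc <- numeric(d)
    for (j in 1:n) acc <- acc + Ahat[i, j] * drop(h_half[j, ] %*% Wg)
    out[i, ] <- pmax(acc, 0) + h_prev[i, ]
  }
  out
}

# attention readout a_i = softmax(u' tanh(h_i Wa)), z = sum a_i h_i
oracle_readout <- function(hL, Wa, u) {
  n <- nrow(hL)
  s <- numeric(n)
  for (i in 1:n) s[i] <- sum(u * tanh(drop(hL[i, ] %*% Wa)))
  e <- exp(s - max(s)); a <- e / sum(e)
  z <- numeric(ncol(hL))
  for (i in 1:n) z <- z + a[i] * hL[i, ]
  list(a = a, z = z)
}

# whole head from fused features and coordinates, scalar-loop composition
oracle_head <- function(params, fused, coords, config) {
  n <- nrow(fused)
  Epe <- stainmil:::pe_sinusoidal(coords, config$d)
  e <- Epe %*% params$Wp
  h0 <- fused %*% params$Wf + e
  # radius topology by explicit pairwise distances
  adj <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    adj[i, j] <- as.numeric(dij <= config$r)
  }
  non <- 1 - adj
  S <- oracle_similarity(h0, params$Wq0, params$Wk0)
  Aadj <- oracle_masked_softmax(S, adj)
  Anon <- oracle_masked_softmax(S, non)
  lam <- oracle_sigmoid(params$theta_lambda)
  Ahat <- lam * Aadj + (1 - lam) * Anon
  h <- h0
  for (l in seq_len(config$L)) {
    lp <- params$layers[[l]]
    h_half <- oracle_attention_layer(h, Ahat, lp$Wq, lp$Wk, lp$Wv)
    h <- oracle_graph_conv(h_half, h, Ahat, lp$Wg)
  }
  ro <- oracle_readout(h, params$Wa, params$u)
  logits <- drop(ro$z %*% params$Wc) + params$bc
  e2 <- exp(logits - max(logits))
  list(probs = e2 / sum(e2), Ahat = Ahat, a = ro$a, z = ro$z, h0 = h0)
}

# O(n^2) pairwise Mann-Whitney AUC oracle (ties count 1/2)
oracle_auc <- function(true, scores) {
  pos <- scores[true == 1]; neg <- scores[true == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  100 * tot / (length(pos) * length(neg))
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
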