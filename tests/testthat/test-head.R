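test_that("sinusoidal positional embeddings are deterministic and absolute", {
  cfg <- head_config(d = 8)
  hp <- head_init(4, cfg, seed = 1)
  coords <- stainmil:::grid_coords(3, 3)
  e1 <- embed_positions(hp, coords, cfg)
  e2 <- embed_positions(hp, coords, cfg)
  expect_identical(e1$e, e2$e)
  # identical coords -> identical embeddings
  two <- rbind(coords[5, ], coords[5, ])
  et <- embed_positions(hp, two, cfg)
  expect_identical(et$e[1, ], et$e[2, ])
  # at the origin all sine components are 0 and cosine components 1
  E0 <- stainmil:::pe_sinusoidal(matrix(c(0L, 0L), 1), 8)
  expect_equal(E0[1, ], rep(c(0, 1), 4))
  # translation changes the (absolute) encoding
  sh <- embed_positions(hp, coords + 2L, cfg)
  expect_gt(max(abs(sh$e - e1$e)), 0.01)
  bad_cfg <- cfg; bad_cfg$pe <- "fourier"
  expect_error(embed_positions(hp, coords, bad_cfg), "unknown positional encoding")
})

test_that("node initialization is the projected feature plus embedding", {
  set.seed(2)
  fused <- matrix(rnorm(4 * 3), 4, 3)
  e <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(init_nodes(fused, e * 0, diag(3)), fused)
  expect_equal(init_nodes(fused * 0, e, diag(3)), e)
  Wf <- matrix(rnorm(9), 3, 3)
  got <- init_nodes(fused, e, Wf)
  manual <- t(vapply(1:4, function(i) {
    vapply(1:3, function(a) sum(fused[i, ] * Wf[, a]) + e[i, a], numeric(1))
  }, numeric(3)))
  expect_equal(got, manual)
  expect_error(init_nodes(fused, e[1:2, ], diag(3)), "row count mismatch")
})

test_that("radius topology matches brute force and satisfies the complement identity", {
  coords <- stainmil:::grid_coords(2, 2)
  topo <- build_topology(coords, 1)
  # each corner of a 2x2 grid: itself + 2 orthogonal neighbors (diagonal sqrt(2) > 1)
  expect_equal(rowSums(topo$adj), rep(3, 4))
  expect_equal(diag(topo$adj), rep(1, 4))
  expect_true(all(topo$adj + topo$non == 1))
  expect_identical(topo$adj, t(topo$adj))
  # r beyond the grid diameter leaves no non-adjacent pairs
  topo_all <- build_topology(coords, 10)
  expect_true(all(topo_all$non == 0))
  # single node
  t1 <- build_topology(matrix(c(0L, 0L), 1), 1.5)
  expect_equal(t1$adj, matrix(1, 1, 1))
  expect_equal(t1$non, matrix(0, 1, 1))
  expect_error(build_topology(coords, 0), "positive")
})

test_that("similarity scores equal the scalar-loop oracle", {
  set.seed(4)
  h0 <- matrix(rnorm(5 * 6), 5, 6)
  Wq <- matrix(rnorm(36), 6, 6); Wk <- matrix(rnorm(36), 6, 6)
  expect_equal(similarity_scores(h0, Wq, Wk), oracle_similarity(h0, Wq, Wk))
  expect_equal(similarity_scores(h0 * 0, Wq, Wk), matrix(0, 5, 5))
  # orthonormal states with identity projections give I / sqrt(d)
  expect_equal(similarity_scores(diag(5), diag(5), diag(5)), diag(5) / sqrt(5))
})

test_that("masked softmax is row-stochastic on support and zero elsewhere", {
  set.seed(6)
  coords <- stainmil:::grid_coords(2, 3)
  topo <- build_topology(coords, 1)
  S <- matrix(rnorm(36), 6, 6)
  A_adj <- masked_softmax(S, topo$adj)
  A_non <- masked_softmax(S, topo$non)
  expect_equal(A_adj, oracle_masked_softmax(S, topo$adj))
  expect_equal(A_non, oracle_masked_softmax(S, topo$non))
  expect_equal(rowSums(A_adj), rep(1, 6), tolerance = 1e-6)
  expect_true(all(A_adj[topo$adj == 0] == 0))
  expect_true(all(A_non[topo$non == 0] == 0))
  # constant scores on a support of size k -> uniform 1/k
  Sc <- matrix(0, 6, 6)
  Ac <- masked_softmax(Sc, topo$adj)
  k <- rowSums(topo$adj)
  expect_equal(Ac[topo$adj > 0], (1 / k[row(topo$adj)])[topo$adj > 0])
  # single node: empty non-adjacent support gives zeros, no NaN
  t1 <- build_topology(matrix(c(0L, 0L), 1), 1.5)
  A1 <- masked_softmax(matrix(0.7, 1, 1), t1$non)
  expect_identical(A1, matrix(0, 1, 1))
  expect_false(any(is.nan(A1)))
})

test_that("structure fusion is a convex combination with row sums preserved", {
  set.seed(8)
  coords <- stainmil:::grid_coords(3, 3)
  topo <- build_topology(coords, 1)  # r = 1: every node keeps non-adjacent pairs
  S <- matrix(rnorm(81), 9, 9)
  Aa <- masked_softmax(S, topo$adj)
  An <- masked_softmax(S, topo$non)
  expect_equal(fuse_structure(Aa, An, 1), Aa)
  expect_equal(fuse_structure(Aa, An, 0), An)
  lam <- 0.37
  Ah <- fuse_structure(Aa, An, lam)
  expect_equal(rowSums(Ah), rep(1, 9), tolerance = 1e-6)  # both supports nonempty
  expect_error(fuse_structure(Aa, An, 1.2), "lambda")
})

test_that("attention layer and graph convolution match scalar-loop oracles", {
  set.seed(10)
  d <- 6
  for (trial in 1:5) {
    h <- matrix(rnorm(5 * d), 5, d)
    Ahat <- matrix(runif(25), 5, 5)
    lp <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
               Wv = matrix(rnorm(d * d), d), Wg = matrix(rnorm(d * d), d))
    got <- graph_attention_layer(h, Ahat, lp)
    expect_equal(got$h_half, oracle_attention_layer(h, Ahat, lp$Wq, lp$Wk, lp$Wv),
                 tolerance = 1e-10)
    conv <- dynamic_graph_conv(got$h_half, h, Ahat, lp$Wg)
    expect_equal(conv$h_next, oracle_graph_conv(got$h_half, h, Ahat, lp$Wg),
                 tolerance = 1e-10)
  }
  # single node: inner softmax is 1, output Ahat_11 * h Wv
  h1 <- matrix(rnorm(d), 1, d)
  A1 <- matrix(0.6, 1, 1)
  lp <- list(Wq = diag(d), Wk = diag(d), Wv = matrix(rnorm(d * d), d))
  expect_equal(graph_attention_layer(h1, A1, lp)$h_half, 0.6 * h1 %*% lp$Wv)
  # annihilation by a zero structure matrix
  h5 <- matrix(rnorm(5 * d), 5, d)
  expect_equal(graph_attention_layer(h5, matrix(0, 5, 5), lp)$h_half, matrix(0, 5, d))
  # Wg = 0: relu(0) + h_prev = h_prev
  expect_equal(dynamic_graph_conv(h5, h5, diag(5), matrix(0, d, d))$h_next, h5)
})

test_that("readout is a convex aggregation matching its oracle", {
  set.seed(12)
  d <- 5
  hL <- matrix(rnorm(6 * d), 6, d)
  Wa <- matrix(rnorm(d * d), d); u <- rnorm(d)
  ro <- readout(hL, Wa, u)
  orc <- oracle_readout(hL, Wa, u)
  expect_equal(ro$a, orc$a)
  expect_equal(ro$z, orc$z)
  expect_equal(sum(ro$a), 1, tolerance = 1e-6)
  expect_true(all(ro$a >= 0))
  # convex hull: z lies within per-coordinate bounds of the states
  expect_true(all(ro$z >= apply(hL, 2, min) - 1e-12 & ro$z <= apply(hL, 2, max) + 1e-12))
  # identical states -> uniform weights and z equals the common state
  hsame <- matrix(rep(rnorm(d), each = 4), 4, d)
  ro2 <- readout(hsame, Wa, u)
  expect_equal(ro2$a, rep(0.25, 4))
  expect_equal(ro2$z, hsame[1, ])
  # single node
  ro3 <- readout(hL[1, , drop = FALSE], Wa, u)
  expect_equal(ro3$a, 1)
  expect_equal(ro3$z, hL[1, ])
})

test_that("classifier outputs the closed-form softmax", {
  expect_equal(classify(c(0, 0), diag(2), c(0, 0))$probs, c(0.5, 0.5))
  big <- classify(c(40, -40), diag(2), c(0, 0))$probs
  expect_equal(big, c(1, 0), tolerance = 1e-12)
  p <- classify(c(1, -1), diag(2), c(0, 0))$probs
  expect_equal(p, c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)))
  expect_equal(sum(p), 1)
})

test_that("full head equals the scalar-loop composition for all N <= 16", {
  set.seed(14)
  for (grid in list(c(1, 1), c(2, 2), c(2, 3), c(4, 4))) {
    C <- 4
    cfg <- head_config(d = 8, L = 2)
    hp <- head_init(C, cfg, seed = grid[1] * 10 + grid[2])
    fused <- matrix(rnorm(prod(grid) * C), prod(grid), C)
    coords <- stainmil:::grid_coords(grid[1], grid[2])
    got <- head_forward(hp, fused, coords, cfg)
    orc <- oracle_head(hp, fused, coords, cfg)
    expect_equal(got$probs, orc$probs, tolerance = 1e-5)
    expect_equal(got$Ahat, orc$Ahat, tolerance = 1e-5)
    expect_equal(got$a, orc$a, tolerance = 1e-5)
    expect_equal(sum(got$probs), 1, tolerance = 1e-6)
    # row sums of Ahat: lambda * [adj nonempty] + (1 - lambda) * [non nonempty]
    topo <- build_topology(coords, cfg$r)
    lam <- 1 / (1 + exp(-hp$theta_lambda))
    expected_rs <- unname(lam * (rowSums(topo$adj) > 0) + (1 - lam) * (rowSums(topo$non) > 0))
    expect_equal(rowSums(got$Ahat), expected_rs, tolerance = 1e-6)
    # mask complement: each normalized matrix vanishes off its support
    S <- similarity_scores(orc$h0, hp$Wq0, hp$Wk0)
    expect_true(all(masked_softmax(S, topo$adj)[topo$non > 0] == 0))
    expect_true(all(masked_softmax(S, topo$non)[topo$adj > 0] == 0))
  }
})

test_that("single-layer head equals the manual composition", {
  set.seed(16)
  C <- 3
  cfg <- head_config(d = 6, L = 1)
  hp <- head_init(C, cfg, seed = 4)
  fused <- matrix(rnorm(9 * C), 9, C)
  coords <- stainmil:::grid_coords(3, 3)
  auto <- head_forward(hp, fused, coords, cfg)
  emb <- embed_positions(hp, coords, cfg)
  h0 <- init_nodes(fused, emb$e, hp$Wf)
  topo <- build_topology(coords, cfg$r)
  S <- similarity_scores(h0, hp$Wq0, hp$Wk0)
  Ah <- fuse_structure(masked_softmax(S, topo$adj), masked_softmax(S, topo$non),
                       1 / (1 + exp(-hp$theta_lambda)))
  att <- graph_attention_layer(h0, Ah, hp$layers[[1]])
  conv <- dynamic_graph_conv(att$h_half, h0, Ah, hp$layers[[1]]$Wg)
  ro <- readout(conv$h_next, hp$Wa, hp$u)
  cl <- classify(ro$z, hp$Wc, hp$bc)
  expect_equal(auto$probs, cl$probs, tolerance = 1e-12)
})

test_that("renormalized attention restores row-stochastic products", {
  set.seed(18)
  cfg <- head_config(d = 6, L = 1, renormalize_attention = TRUE)
  hp <- head_init(3, cfg, seed = 5)
  fused <- matrix(rnorm(9 * 3), 9, 3)
  coords <- stainmil:::grid_coords(3, 3)
  out <- head_forward(hp, fused, coords, cfg)
  att <- graph_attention_layer(matrix(rnorm(9 * 6), 9, 6), out$Ahat,
                               hp$layers[[1]], renormalize = TRUE)
  expect_equal(rowSums(att$cache$M), rep(1, 9), tolerance = 1e-9)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
})

test_that("every head parameter receives gradient from the cross-entropy loss", {
  set.seed(20)
  C <- 4
  cfg <- head_config(d = 6, L = 2)
  hp <- head_init(C, cfg, seed = 6)
  fused <- matrix(rnorm(16 * C), 16, C)
  coords <- stainmil:::grid_coords(4, 4)
  fw <- head_forward(hp, fused, coords, cfg)
  dlogits <- fw$probs - c(0, 1)
  bk <- stainmil:::head_backward(hp, fw$cache, dlogits)
  flat <- stainmil:::flatten_params(bk$grads)
  for (nm in names(flat)) expect_gt(max(abs(flat[[nm]])), 0, label = nm)
  # and they agree with finite differences
  loss_fn <- function(params) -log(head_forward(params, fused, coords, cfg)$probs[2])
  worst <- fd_check_grads(loss_fn, hp, bk$grads, n_entries = 2)
  expect_lt(worst, 1e-4)
})
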