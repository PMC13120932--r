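# Small fixtures built in code.

random_tokens <- function(gh, gw, C, seed = 1) {
  set.seed(seed)
  token_grid(matrix(rnorm(gh * gw * C), gh * gw, C), c(gh, gw))
}

tiny_model <- function(side = 32L, C = 6L, d = 8L, L = 2L, window = 2L,
                       ablate = FALSE, seed = 5L) {
  model_init(side = side,
             backbone = backbone_mini(channels = C, hidden = 5L, seed = seed),
             sda_window = window, head = head_config(d = d, L = L),
             ablate_sda = ablate, seed = seed)
}

random_image <- function(side = 32L, seed = 1) {
  set.seed(seed)
  array(runif(side * side * 3), c(side, side, 3))
}

# smaller nuclei so dense class-1 images fit on 32-px test canvases
small_morph <- function() morphology_spec(radius_mean = 2, radius_sd = 0.3)

# central finite-difference gradient for a scalar-valued function of the
# parameter tree, evaluated at a few sampled entries per leaf
fd_check_grads <- function(loss_fn, params, grads, n_entries = 3L, eps = 1e-5,
                           seed = 1L) {
  fg <- stainmil:::flatten_params(grads)
  fp <- stainmil:::flatten_params(params)
  set.seed(seed)
  worst <- 0
  perturb <- function(tree, path, idx, delta) {
    ks <- strsplit(path, ".", fixed = TRUE)[[1]]
    rec <- function(t, ks) {
      k <- ks[1]
      k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      if (length(ks) == 1) { t[[k2]][idx] <- t[[k2]][idx] + delta; t }
      else { t[[k2]] <- rec(t[[k2]], ks[-1]); t }
    }
    rec(tree, ks)
  }
  for (nm in names(fp)) {
    v <- fp[[nm]]
    ii <- if (length(v) <= n_entries) seq_along(v) else sample(length(v), n_entries)
    for (i in ii) {
      num <- (loss_fn(perturb(params, nm, i, eps)) -
              loss_fn(perturb(params, nm, i, -eps))) / (2 * eps)
      ana <- fg[[nm]][i]
      rel <- abs(num - ana) / max(1e-6, abs(num), abs(ana))
      worst <- max(worst, rel)
    }
  }
  worst
}
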