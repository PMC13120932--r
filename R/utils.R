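# Small numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax with max-subtraction stabilisation
#' @param x numeric matrix
#' @return matrix of same shape, rows summing to 1
#' @noRd
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

relu <- function(x) pmax(x, 0)

# Flatten a nested list of numeric arrays into a single named numeric vector,
# and back. Used by the optimizer, gradient clipping and finite-difference
# checks; names encode the path ("sda.ws1" etc.).
flatten_params <- function(p, prefix = NULL) {
  out <- list()
  keys <- names(p) %||% as.character(seq_along(p))
  for (i in seq_along(p)) {
    key <- if (is.null(prefix)) keys[i] else paste(prefix, keys[i], sep = ".")
    v <- p[[i]]
    if (is.list(v)) {
      out <- c(out, flatten_params(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

# Apply f(elementwise) jointly over two parameter trees of identical shape.
# Subtrees are matched by name where available, by position otherwise
# (e.g. the head's per-layer parameter list).
map2_params <- function(a, b, f) {
  out <- a
  nms <- names(a)
  for (i in seq_along(a)) {
    bi <- if (is.null(nms) || nms[i] == "") b[[i]] else b[[nms[i]]]
    if (is.list(a[[i]])) {
      out[[i]] <- map2_params(a[[i]], bi, f)
    } else {
      out[[i]] <- f(a[[i]], bi)
    }
  }
  out
}

map_params <- function(a, f) {
  out <- a
  for (i in seq_along(a)) {
    if (is.list(a[[i]])) out[[i]] <- map_params(a[[i]], f) else out[[i]] <- f(a[[i]])
  }
  out
}

# Sum of squares over a parameter tree (for global-norm gradient clipping).
params_sumsq <- function(p) {
  s <- 0
  for (v in flatten_params(p)) s <- s + sum(v * v)
  s
}

zeros_like <- function(p) map_params(p, function(x) x * 0)

# Gaussian init scaled like Glorot for a dim-in fan.
init_mat <- function(nr, nc, scale = sqrt(2 / (nr + nc))) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}
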