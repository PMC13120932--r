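# Deterministic synthetic histology-like image generator.
#
# Class identity is carried by a morphological statistic (nuclei density,
# with class-specific boundary irregularity); stain style is a per-domain
# affine transform in optical-density (OD) space, mimicking Beer-Lambert
# stain physics: I = exp(-OD), OD' = gain * OD + offset. A confound
# parameter rho in [-1, 1] controls how strongly the stain domain correlates
# with the class label within a split, which is what makes color-shortcut
# learning reproducible and measurable.

#' Morphology specification for the two synthetic classes
#'
#' @param count_range_0,count_range_1 integer nuclei-count intervals for the
#'   Normal-like (class 0) and OSCC-like (class 1) class; must be disjoint so
#'   the recorded statistic determines the label.
#' @param radius_mean,radius_sd nucleus radius in pixels.
#' @param irregularity_0,irregularity_1 dimensionless boundary irregularity
#'   amplitude per class (>= 0).
#' @param texture_scale background texture correlation length in pixels.
#' @return a `morphology_spec` list.
#' @export
morphology_spec <- function(count_range_0 = c(6L, 12L), count_range_1 = c(18L, 28L),
                            radius_mean = 3.5, radius_sd = 0.6,
                            irregularity_0 = 0.15, irregularity_1 = 0.45,
                            texture_scale = 8) {
  if (max(count_range_0) >= min(count_range_1)) {
    stop("class nuclei-count ranges must be disjoint (class 1 higher)", call. = FALSE)
  }
  if (any(c(radius_mean, radius_sd, texture_scale) <= 0) ||
      any(c(irregularity_0, irregularity_1) < 0)) {
    stop("morphology parameters must be positive (irregularity >= 0)", call. = FALSE)
  }
  structure(list(count_range_0 = as.integer(count_range_0),
                 count_range_1 = as.integer(count_range_1),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 irregularity_0 = irregularity_0, irregularity_1 = irregularity_1,
                 texture_scale = texture_scale),
            class = "morphology_spec")
}

#' Per-domain stain style: affine transform in optical-density space
#'
#' @param gain length-3 positive per-channel OD gains.
#' @param offset length-3 per-channel OD offsets.
#' @param id domain identifier.
#' @return a `domain_style` list. The identity style is gain (1,1,1),
#'   offset (0,0,0).
#' @export
domain_style <- function(gain = c(1, 1, 1), offset = c(0, 0, 0), id = "identity") {
  if (any(gain <= 0)) stop("OD gains must be positive", call. = FALSE)
  structure(list(gain = gain, offset = offset, id = id), class = "domain_style")
}

# Two default laboratory styles: an eosin-leaning (pinker) and a
# hematoxylin-leaning (more purple/blue) staining protocol.
default_domains <- function() {
  list(
    domain_style(gain = c(1.25, 0.80, 1.05), offset = c(0.04, 0.01, 0.02), id = "lab_pink"),
    domain_style(gain = c(0.80, 1.25, 0.95), offset = c(0.01, 0.05, 0.03), id = "lab_purple")
  )
}

#' Apply / invert a stain style in optical-density space
#'
#' `apply_style` maps intensities through `exp(-(gain * OD + offset))`;
#' `invert_style` applies the exact inverse transform.
#'
#' @param img H x W x 3 array in (0, 1\].
#' @param style a `domain_style`.
#' @return transformed image array.
#' @export
apply_style <- function(img, style) {
  if (all(style$gain == 1) && all(style$offset == 0)) return(img)  # exact identity
  out <- img
  for (ch in 1:3) {
    od <- -log(pmax(img[, , ch], 1e-6))
    out[, , ch] <- exp(-(style$gain[ch] * od + style$offset[ch]))
  }
  out
}

#' @rdname apply_style
#' @export
invert_style <- function(img, style) {
  out <- img
  for (ch in 1:3) {
    od <- -log(pmax(img[, , ch], 1e-12))
    out[, , ch] <- exp(-((od - style$offset[ch]) / style$gain[ch]))
  }
  out
}

#' Dataset specification for the synthetic generator
#'
#' @param n_per_class integer vector `c(n0, n1)` (class 0 = Normal-like).
#' @param side image side in pixels (default 64).
#' @param domains list of [domain_style()]s (default: two laboratory styles).
#' @param rho label-domain confound strength in \[-1, 1\]: 0 decorrelates
#'   label and domain exactly (up to count rounding), 1 assigns each class
#'   its own domain.
#' @param morph a [morphology_spec()].
#' @param seed integer seed; (spec, seed) fully determines every image byte.
#' @param ratios train/val/test split ratios.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = c(120L, 280L), side = 64L,
                           domains = default_domains(), rho = 0,
                           morph = morphology_spec(), seed = 7L,
                           ratios = c(0.7, 0.1, 0.2)) {
  if (sum(n_per_class) < 2L) stop("need at least 2 images", call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (length(domains) != 2L && rho != 0) {
    stop("label-domain confounding is defined for exactly 2 domains", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class), side = as.integer(side),
                 domains = domains, rho = rho, morph = morph,
                 seed = as.integer(seed), ratios = ratios),
            class = "synthetic_spec")
}

#' Render one synthetic histology-like image
#'
#' Places `k` irregular nuclear blobs (class-specific count range and
#' boundary irregularity) on a smooth textured background, converts the
#' density map to RGB through hematoxylin/eosin-like OD vectors, and applies
#' the domain's OD-space affine style. Consumes the current RNG stream.
#'
#' @param morph a [morphology_spec()].
#' @param style a [domain_style()].
#' @param label class label (0 or 1).
#' @param side image side in pixels.
#' @return list(pixels = side x side x 3 array in \[0, 1\] quantized to 8
#'   bits, stat = nuclei count, n_placed = nuclei actually drawn).
#' @export
render_image <- function(morph, style, label, side = 64L) {
  rng <- function(n, lo, hi) stats::runif(n, lo, hi)
  cr <- if (label == 1) morph$count_range_1 else morph$count_range_0
  irr <- if (label == 1) morph$irregularity_1 else morph$irregularity_0
  k <- sample(cr[1]:cr[2], 1L)
  # nuclei may overlap; refuse only absurd packings (> 60% canvas coverage)
  max_fit <- floor(0.6 * side^2 / (pi * morph$radius_mean^2))
  if (k > max_fit) {
    stop(sprintf("cannot place %d nuclei of mean radius %.1f on a %d px canvas",
                 k, morph$radius_mean, side), call. = FALSE)
  }
  # smooth background texture: coarse Gaussian noise, bilinearly upsampled
  nc <- max(2L, ceiling(side / morph$texture_scale))
  coarse <- matrix(stats::rnorm(nc * nc, mean = 0.25, sd = 0.06), nc, nc)
  bg <- as.array(EBImage::resize(coarse, w = side, h = side))
  bg <- pmin(pmax(bg, 0), 0.6)
  dens <- matrix(0, side, side)
  xs <- matrix(rep(seq_len(side), each = side), side)   # column index per cell
  ys <- matrix(rep(seq_len(side), times = side), side)  # row index per cell
  for (b in seq_len(k)) {
    cx <- rng(1, 1 + morph$radius_mean, side - morph$radius_mean)
    cy <- rng(1, 1 + morph$radius_mean, side - morph$radius_mean)
    r0 <- max(1.5, stats::rnorm(1, morph$radius_mean, morph$radius_sd))
    a1 <- rng(1, 0.5, 1); a2 <- rng(1, 0.5, 1)
    ph1 <- rng(1, 0, 2 * pi); ph2 <- rng(1, 0, 2 * pi)
    dx <- xs - cx; dy <- ys - cy
    dd <- sqrt(dx^2 + dy^2)
    near <- dd <= r0 * (1 + 2 * irr) + 1
    th <- atan2(dy[near], dx[near])
    rb <- r0 * (1 + irr * (a1 * sin(2 * th + ph1) + a2 * sin(3 * th + ph2)) / (a1 + a2))
    inside <- near
    inside[near] <- dd[near] <= rb
    dens[inside] <- pmin(dens[inside] + 0.85, 1)
  }
  # OD composition: nuclei absorb like hematoxylin, background like eosin
  od_nuc <- c(0.65, 0.70, 0.29)
  od_bg <- c(0.10, 0.55, 0.15)
  img <- array(0, c(side, side, 3L))
  for (ch in 1:3) img[, , ch] <- exp(-(dens * od_nuc[ch] * 2.2 + bg * od_bg[ch]))
  img <- apply_style(img, style)
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255   # 8-bit quantization
  list(pixels = img, stat = k, n_placed = k)
}

# Deterministic domain assignment achieving label-domain correlation rho:
# for class c, round(n_c * (1 + rho) / 2) images go to the class-aligned
# domain (class 0 -> domain 1, class 1 -> domain 2), the rest to the other.
assign_domains <- function(n_per_class, rho, ndom = 2L) {
  if (ndom != 2L) {  # >2 (or 1) domains: decorrelated round-robin (rho = 0)
    return(lapply(1:2, function(cl) rep_len(seq_len(ndom), n_per_class[cl])))
  }
  lapply(1:2, function(cl) {
    n <- n_per_class[cl]
    n_match <- round(n * (1 + rho) / 2)
    c(rep(cl, n_match), rep(3L - cl, n - n_match))
  })
}

#' Generate a synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory: when given, images are written as
#'   PNG files and `manifest$path` points at them; when NULL images stay in
#'   memory as `attr(manifest, "images")`.
#' @param split_seed seed for the stratified split assignment (defaults to
#'   `spec$seed`).
#' @return a tibble manifest with columns `path`, `label`, `domain`, `stat`,
#'   `split`; in-memory pixel arrays in `attr(, "images")`.
#' @export
generate_dataset <- function(spec, dir = NULL, split_seed = NULL) {
  n0 <- spec$n_per_class[1]; n1 <- spec$n_per_class[2]
  labels <- c(rep(0L, n0), rep(1L, n1))
  doms <- assign_domains(spec$n_per_class, spec$rho, length(spec$domains))
  domain_idx <- c(doms[[1]], doms[[2]])
  set.seed(spec$seed)
  # shuffle domain assignment within class so domain is independent of
  # placement order
  domain_idx[labels == 0L] <- sample(domain_idx[labels == 0L])
  domain_idx[labels == 1L] <- sample(domain_idx[labels == 1L])
  images <- vector("list", length(labels))
  stats_ <- integer(length(labels))
  for (i in seq_along(labels)) {
    r <- render_image(spec$morph, spec$domains[[domain_idx[i]]], labels[i], spec$side)
    images[[i]] <- r$pixels
    stats_[i] <- r$stat
  }
  split <- stratified_split(labels, spec$ratios, seed = split_seed %||% spec$seed)
  path <- rep(NA_character_, length(labels))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, sprintf("img_%04d_c%d_d%d.png", seq_along(labels),
                                   labels, domain_idx))
    for (i in seq_along(labels)) png::writePNG(images[[i]], path[i])
  }
  manifest <- tibble::tibble(
    path = path, label = labels,
    domain = vapply(domain_idx, function(j) spec$domains[[j]]$id, character(1)),
    stat = stats_, split = split
  )
  attr(manifest, "images") <- images
  manifest
}

#' Generate a distribution-shifted replacement test set
#'
#' Rebuilds the test split of `spec` with either a different label-domain
#' confound (`mode = "rho"`, default `rho_test = 0`) or entirely held-out
#' domain styles (`mode = "holdout"`), leaving morphology parameters
#' untouched.
#'
#' @param spec the [synthetic_spec()] used for training data.
#' @param n_per_class test-set class counts; defaults to the `spec` test
#'   share (0.2 of each class, by the split rounding rule).
#' @param mode "rho" or "holdout".
#' @param rho_test confound in the new test set (mode "rho").
#' @param holdout_domains list of unseen [domain_style()]s (mode "holdout").
#' @param dir optional output directory.
#' @return a manifest tibble (all rows tagged split = "test").
#' @export
shifted_test_set <- function(spec, n_per_class = NULL, mode = c("rho", "holdout"),
                             rho_test = 0, holdout_domains = NULL, dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_per_class)) {
    n_per_class <- vapply(spec$n_per_class, function(n) {
      as.integer(n - round(spec$ratios[1] * n) - round(spec$ratios[2] * n))
    }, integer(1))
  }
  sub <- spec
  sub$n_per_class <- as.integer(n_per_class)
  sub$seed <- spec$seed + 1000003L
  if (mode == "rho") {
    sub$rho <- rho_test
  } else {
    if (is.null(holdout_domains)) stop("holdout mode needs `holdout_domains`", call. = FALSE)
    train_ids <- vapply(spec$domains, `[[`, character(1), "id")
    new_ids <- vapply(holdout_domains, `[[`, character(1), "id")
    if (any(new_ids %in% train_ids)) stop("holdout domains overlap training domains", call. = FALSE)
    sub$domains <- holdout_domains
    sub$rho <- 0
  }
  sub$ratios <- c(0, 0, 1)
  m <- generate_dataset_all_split(sub, "test", dir)
  m
}

# generate with every sample assigned one fixed split tag (used for shifted
# test sets, where no further splitting is meaningful)
generate_dataset_all_split <- function(spec, tag, dir = NULL) {
  spec2 <- spec
  spec2$ratios <- c(0.7, 0.1, 0.2)  # placeholder; split overwritten below
  m <- generate_dataset(spec2, dir = dir)
  imgs <- attr(m, "images")
  m$split <- tag
  attr(m, "images") <- imgs
  m
}
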