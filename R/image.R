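# Image decoding, resizing and channel normalization.
#
# Images are plain R arrays H x W x 3 with values in [0, 1] ("image tensors").
# Normalized tensors (after mean/std scaling) keep the same layout but may
# leave [0, 1]; they are what the backbone consumes.

#' Load an RGB image from a PNG file
#'
#' @param path path to a PNG file.
#' @return an H x W x 3 array in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s' (no such file)", path), call. = FALSE)
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop(sprintf("unsupported image format for '%s' (PNG expected)", path), call. = FALSE)
  }
  px <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("failed to decode image '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  to_rgb_array(px, path)
}

to_rgb_array <- function(px, what = "image") {
  if (length(dim(px)) == 2L) {
    stop(sprintf("non-RGB input for %s: grayscale image (3 channels required)", what), call. = FALSE)
  }
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3] != 3L) {
    stop(sprintf("non-RGB input for %s: %d channels", what, dim(px)[3]), call. = FALSE)
  }
  px
}

validate_image_tensor <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) stop("image must be an H x W x 3 array", call. = FALSE)
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1) stop("image channel values must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

#' Resize an RGB image and apply channel normalization
#'
#' Bilinearly resizes to a square `side x side` target and then standardizes
#' each channel as `(x - mean) / sd`. The defaults (mean 0.5, sd 0.5 per
#' channel) map \[0, 1\] pixels to \[-1, 1\]; use the ImageNet constants when
#' plugging in a pretrained backbone adapter.
#'
#' @param raw an H x W x 3 array in \[0, 1\], or a path to a PNG file.
#' @param side target side length in pixels (default 224).
#' @param mean,sd per-channel normalization constants (length 3 or scalar).
#' @return a `side x side x 3` numeric array (normalized; not clamped).
#' @export
resize_and_normalize <- function(raw, side = 224L,
                                 mean = c(0.5, 0.5, 0.5),
                                 sd = c(0.5, 0.5, 0.5)) {
  if (is.character(raw)) raw <- load_image(raw)
  validate_image_tensor(raw)
  mean <- rep_len(mean, 3L); sd <- rep_len(sd, 3L)
  if (any(sd <= 0)) stop("normalization sd must be positive", call. = FALSE)
  d <- dim(raw)
  if (d[1] != side || d[2] != side) {
    raw <- as.array(EBImage::resize(raw, w = side, h = side))
  }
  out <- array(0, c(side, side, 3L))
  for (ch in 1:3) out[, , ch] <- (raw[, , ch] - mean[ch]) / sd[ch]
  out
}
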