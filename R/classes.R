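# Class codes used throughout: 0 = background, 1 = cell body, 2 = neurite.
# The CNN channel order is (background, cell_body, neurite), in that order.

LBL_BACKGROUND <- 0L
LBL_BODY <- 1L
LBL_NEURITE <- 2L

#' Phase image container
#'
#' A 2-D phase raster with its pixel pitch.  Three unit conventions are
#' used along the pipeline: `"radians"` for measured/synthetic phase maps,
#' `"normalized"` for values scaled to \[0, 1\] (network input), and
#' `"uint8"` for quantized 0--255 images (stored PNGs).
#'
#' @param values numeric matrix
#' @param pixel_pitch_um physical pixel size in micrometers
#' @param units one of `"radians"`, `"normalized"`, `"uint8"`
#' @return a `phase_image` (matrix with attributes)
#' @export
phase_image <- function(values, pixel_pitch_um = 0.69,
                        units = c("normalized", "radians", "uint8")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (units == "normalized" && (min(values) < 0 || max(values) > 1))
    stop("normalized phase images must lie in [0, 1]")
  if (units == "uint8" && (min(values) < 0 || max(values) > 255))
    stop("uint8 phase images must lie in [0, 255]")
  structure(values, class = c("phase_image", "matrix"),
            pixel_pitch_um = pixel_pitch_um, units = units)
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image %dx%d px, pitch %.3f um, units %s, range [%.3g, %.3g]>\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch_um"), attr(x, "units"),
              min(x), max(x)))
  invisible(x)
}

#' @export
plot.phase_image <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(x) / ncol(x), ...)
  invisible(x)
}

#' Three-class label image container
#'
#' Integer raster over \{0 background, 1 cell body, 2 neurite\}.
#'
#' @param classes integer matrix with values in \{0, 1, 2\}
#' @param pixel_pitch_um physical pixel size in micrometers
#' @return a `label_image`
#' @export
label_image <- function(classes, pixel_pitch_um = 0.69) {
  if (!is.matrix(classes)) stop("classes must be a matrix")
  cl <- matrix(as.integer(classes), nrow(classes), ncol(classes))
  if (!all(cl %in% c(0L, 1L, 2L))) stop("label classes must be 0, 1 or 2")
  structure(cl, class = c("label_image", "matrix"),
            pixel_pitch_um = pixel_pitch_um)
}

#' @export
print.label_image <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<label_image %dx%d px, pitch %.3f um | bg %.1f%%, body %.1f%%, neurite %.1f%%>\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch_um"),
              100 * sum(x == 0L) / n, 100 * sum(x == 1L) / n, 100 * sum(x == 2L) / n))
  invisible(x)
}

#' @export
plot.label_image <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1], col = c("black", "red", "green3"),
                  breaks = c(-0.5, 0.5, 1.5, 2.5), axes = FALSE,
                  asp = nrow(x) / ncol(x), ...)
  invisible(x)
}

# one-hot encode a label matrix into an (H*W) x 3 matrix, channel order
# (background, cell_body, neurite)
label_onehot <- function(label) {
  v <- as.integer(label)
  cbind(background = as.numeric(v == 0L),
        cell_body = as.numeric(v == 1L),
        neurite = as.numeric(v == 2L))
}

#' Derive a reproducible sub-seed from a base seed and a stream name
#'
#' The multi-stage pipeline fans a single user seed out to named substreams
#' (placement, noise, augmentation, ...) so that stages can be replayed
#' independently.  Plain integer hashing; result is always in \[0, 2^31).
#'
#' @param seed integer base seed
#' @param name character stream name
#' @return integer sub-seed
#' @export
derive_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}
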