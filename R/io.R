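# File formats: 8-bit grayscale PNG for images, 8-bit RGB PNG for labels
# (red = cell body, green = neurite, black = background, channels
# saturated to 255), 32-bit float TIFF for phase maps in radians, CSV for
# tables.  Everything written here is re-readable by the package's own
# readers.

#' Encode a label image as saturated RGB
#'
#' Cell body becomes (255, 0, 0), neurite (0, 255, 0) and background
#' (0, 0, 0).
#'
#' @param label a `label_image`
#' @return H x W x 3 numeric array with values 0 or 255
#' @export
encode_label <- function(label) {
  m <- unclass(label)
  rgb <- array(0, dim = c(nrow(m), ncol(m), 3))
  rgb[, , 1][m == LBL_BODY] <- 255
  rgb[, , 2][m == LBL_NEURITE] <- 255
  rgb
}

#' Decode an RGB raster into a label image
#'
#' Pixels are mapped to the nearest of the three sanctioned colors
#' (black, saturated red, saturated green); if any pixel is not exactly
#' one of them a warning reports how many were snapped.
#'
#' @param rgb H x W x 3 array with values 0--255
#' @param pixel_pitch_um pixel pitch of the returned label
#' @return a `label_image`
#' @export
decode_label <- function(rgb, pixel_pitch_um = 0.69) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3) stop("expected an RGB array")
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  d_bg <- r^2 + g^2 + b^2
  d_body <- (r - 255)^2 + g^2 + b^2
  d_neu <- r^2 + (g - 255)^2 + b^2
  cl <- matrix(LBL_BACKGROUND, nrow(r), ncol(r))
  cl[d_body < d_bg & d_body <= d_neu] <- LBL_BODY
  cl[d_neu < d_bg & d_neu < d_body] <- LBL_NEURITE
  exact <- (d_bg == 0) | (d_body == 0) | (d_neu == 0)
  if (!all(exact))
    warning(sum(!exact), " pixel(s) with unsanctioned colors snapped to the nearest class")
  label_image(cl, pixel_pitch_um = pixel_pitch_um)
}

#' Write / read an 8-bit grayscale image PNG
#' @param image uint8 `phase_image` (or matrix in 0--255)
#' @param path file path
#' @export
write_image_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @param pixel_pitch_um pitch attached to the returned image
#' @export
read_image_png <- function(path, pixel_pitch_um = 0.69) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  phase_image(round(m * 255), pixel_pitch_um, units = "uint8")
}

#' Write / read a 3-class label PNG
#' @param label a `label_image`
#' @param path file path
#' @export
write_label_png <- function(label, path) {
  png::writePNG(encode_label(label) / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @param pixel_pitch_um pitch attached to the returned label
#' @export
read_label_png <- function(path, pixel_pitch_um = 0.69) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3) stop("label PNG must be RGB: ", path)
  decode_label(round(a * 255), pixel_pitch_um)
}

#' Write / read a 32-bit float phase TIFF (radians)
#'
#' Float TIFF samples are stored on \[0, 1\], so the map is scaled by its
#' maximum on write; the scale is carried in a second 1x1 page of the same
#' file (encoded as `s / (1 + s)` to stay on the unit interval) and
#' restored on read, keeping the values in radians end to end.  Negative
#' phase is clipped to zero on write, matching the background-subtraction
#' convention.
#'
#' @param phase `phase_image` in radians
#' @param path file path
#' @export
write_phase_tiff <- function(phase, path) {
  m <- pmax(unclass(phase), 0)
  mx <- max(m, 1e-12)
  tiff::writeTIFF(list(m / mx, matrix(mx / (1 + mx), 1, 1)), path,
                  bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_phase_tiff
#' @param pixel_pitch_um pitch attached to the returned phase map
#' @export
read_phase_tiff <- function(path, pixel_pitch_um = 0.345) {
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- pages[[1]]
  if (length(dim(m)) == 3) m <- m[, , 1]
  scale <- if (length(pages) > 1) {
    enc <- as.numeric(pages[[2]])[1]
    enc / (1 - enc)
  } else 1
  phase_image(matrix(as.numeric(m) * scale, nrow(m), ncol(m)),
              pixel_pitch_um, units = "radians")
}

#' Write an agreement map PNG (blue unanimous, green partial, black none)
#' @param report an `agreement_report`
#' @param path file path
#' @export
write_agreement_png <- function(report, path) {
  png::writePNG(agreement_rgb(report) / 255, path)
  invisible(path)
}

#' Resize a raster to a working resolution
#'
#' Square rasters only.  Intensity images are resampled bilinearly, labels
#' and masks with nearest neighbour (no new classes can appear).  The
#' pixel pitch is rescaled so the physical field is preserved.
#'
#' @param x a `phase_image`, `label_image`, or plain matrix
#' @param target output side in pixels (512 or 1024 in the reference
#'   pipeline, any positive side accepted)
#' @return resized object of the same class
#' @export
resize_to_working <- function(x, target) {
  if (nrow(x) != ncol(x)) stop("resize_to_working expects a square raster")
  if (nrow(x) == target) return(x)
  pitch <- attr(x, "pixel_pitch_um")
  new_pitch <- if (is.null(pitch)) NULL else pitch * nrow(x) / target
  if (inherits(x, "label_image")) {
    m <- resize_matrix(unclass(x), target, target, method = "nearest")
    label_image(matrix(as.integer(round(m)), target, target),
                pixel_pitch_um = new_pitch %||% 0.69)
  } else if (inherits(x, "phase_image")) {
    m <- resize_matrix(unclass(x), target, target, method = "bilinear")
    units <- attr(x, "units")
    if (units == "uint8") m <- clamp(round(m), 0, 255)
    if (units == "normalized") m <- clamp(m, 0, 1)
    phase_image(m, pixel_pitch_um = new_pitch %||% 0.69, units = units)
  } else {
    resize_matrix(x, target, target, method = "bilinear")
  }
}

#' Default run configuration
#'
#' One structured configuration covering every stage's parameters, with
#' every default equal to the reference protocol value where one exists
#' (21x21/sigma-21 scene blur, 0.95 noise threshold, 714 um^2 area filter,
#' 0.5 SoftMax threshold, SGD lr 0.01 / batch 5 / 200 epochs, 51x51
#' consensus window, 10 tie-break iterations).
#'
#' @param seed global seed fanned out to per-stage substreams
#' @return nested list of stage configurations
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       growth = unclass(growth_config(seed = seed)),
       render = list(soma_semiaxis_um_range = c(4, 26), noise_floor = 10,
                     scene_blur_size = 21, scene_blur_sigma = 21,
                     final_blur_size = 3, final_blur_sigma = 1,
                     noise = unclass(noise_config())),
       augment = list(n_generate = 50000, n_subsample = 5000),
       train = list(epochs = 200, batch_size = 5, learning_rate = 0.01,
                    holdout_fraction = 0.1, softmax_threshold = 0.5),
       consensus = list(window = 51, max_iter = 10),
       postproc = list(min_area_um2 = 714,
                       sweep_range = seq(119, 1071, by = 119),
                       connectivity = 8),
       dry_mass = list(wavelength_um = 0.6328, alpha = 0.2,
                       pitch_um = 0.345, mass_grid = 1024))
}

#' Write / read a run configuration as YAML
#' @param cfg nested configuration list
#' @param path file path
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
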