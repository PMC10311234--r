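# Imaging-geometry arithmetic for the off-axis QPI system the pipeline
# emulates: a 10x/0.30 NA objective onto a sensor with 3.45-um pixels,
# 1024x1024 sub-frames.

#' Rayleigh diffraction-limited spot size
#'
#' `0.61 * lambda / NA`, in the same length unit as `lambda`.
#'
#' @param lambda_um wavelength (default 0.633 um)
#' @param na numerical aperture (default 0.30)
#' @return spot radius in micrometers
#' @export
rayleigh_spot_um <- function(lambda_um = 0.633, na = 0.30) {
  if (lambda_um <= 0 || na <= 0) stop("lambda and NA must be positive")
  0.61 * lambda_um / na
}

#' Field of view on the sample
#'
#' Sensor extent divided by the magnification:
#' `n_px * sensor_pitch_um / magnification`.
#'
#' @param n_px pixels across the sub-frame (default 1024)
#' @param sensor_pitch_um physical sensor pixel size (default 3.45 um)
#' @param magnification objective magnification (default 10)
#' @return field of view in micrometers
#' @export
field_of_view_um <- function(n_px = 1024, sensor_pitch_um = 3.45,
                             magnification = 10) {
  n_px * sensor_pitch_um / magnification
}

#' Sample-plane pixel coverage
#'
#' @inheritParams field_of_view_um
#' @return micrometers of sample covered by one sensor pixel
#' @export
pixel_coverage_um <- function(sensor_pitch_um = 3.45, magnification = 10) {
  sensor_pitch_um / magnification
}
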