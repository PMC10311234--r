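# Shared fixtures, generated in code at test time.

# tiny dish configuration for fast simulation tests
tiny_growth_config <- function(...) {
  defaults <- list(field_size_um = 44.16, grid_px = 64L, n_steps = 3L,
                   n_neurons_min = 1L, n_neurons_max = 2L,
                   elongation_mean_um = 6, elongation_sd_um = 1.5)
  do.call(growth_config, utils::modifyList(defaults, list(...)))
}

# a label image with one solid rectangular body and a thin neurite,
# proportionally placed so any raster size works
toy_label <- function(n = 64, pitch = 0.69) {
  m <- matrix(0L, n, n)
  r <- function(f) max(1L, round(n * f))
  m[r(0.16):r(0.39), r(0.19):r(0.48)] <- 1L
  m[r(0.28), (r(0.48) + 1L):r(0.78)] <- 2L
  label_image(m, pixel_pitch_um = pitch)
}

# a uint8 phase image with a bright blob matching toy_label's body
toy_image <- function(n = 64) {
  m <- matrix(0, n, n)
  m[10:25, 12:31] <- 200
  m[18, 32:50] <- 60
  phase_image(m, pixel_pitch_um = 0.69, units = "uint8")
}

# perturb a label by reassigning a given fraction of pixels to random
# other classes (used to emulate imperfect raters)
perturb_label <- function(label, frac, seed) {
  set.seed(seed)
  m <- unclass(label)
  n <- length(m)
  flip <- sample.int(n, round(frac * n))
  m[flip] <- (m[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
  label_image(m, pixel_pitch_um = attr(label, "pixel_pitch_um"))
}
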