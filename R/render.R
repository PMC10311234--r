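# Renderer: turns a neurite skeleton timeline into a "ball and stick"
# image (ellipsoid somata + 1-px neurites), smooths it into a pseudo-QPI
# phase profile, adds blurred speckle/debris noise, and derives the
# matching three-class label automatically.

#' Noise synthesis configuration
#'
#' Speckle/debris noise is made from a uniform random field thresholded at
#' `seed_threshold` (survivors set to `high_value`), then blurred by a
#' cascade of Gaussian filters.  Blur sigmas default to the kernel sizes,
#' matching the 21x21/sigma-21 convention used for the scene blur.
#'
#' @param seed_threshold uniform threshold above which a pixel seeds noise
#'   (default 0.95, i.e. 5% of pixels)
#' @param high_value intensity given to seed pixels (default 255)
#' @param blur_kernel_sizes odd, increasing kernel sizes of the blur cascade
#' @param blur_sigmas per-stage Gaussian sigmas in pixels
#' @return a `noise_config`
#' @export
noise_config <- function(seed_threshold = 0.95, high_value = 255,
                         blur_kernel_sizes = c(3L, 11L, 31L),
                         blur_sigmas = blur_kernel_sizes) {
  if (seed_threshold <= 0 || seed_threshold >= 1)
    stop("seed_threshold must be in (0, 1)")
  if (any(blur_kernel_sizes %% 2 != 1) || is.unsorted(blur_kernel_sizes, strictly = TRUE))
    stop("kernel sizes must be odd and increasing")
  if (length(blur_sigmas) != length(blur_kernel_sizes))
    stop("need one sigma per kernel")
  structure(list(seed_threshold = seed_threshold, high_value = high_value,
                 blur_kernel_sizes = as.integer(blur_kernel_sizes),
                 blur_sigmas = blur_sigmas),
            class = "noise_config")
}

#' Rendering configuration
#'
#' @param soma_semiaxis_um_range uniform range for the per-axis soma
#'   semi-extents in micrometers; the default (4, 26) gives a mean rendered
#'   diameter near 30 um
#' @param noise_floor intensity (0--255 scale) above which the smoothed
#'   soma field is labeled cell body
#' @param scene_blur_size,scene_blur_sigma Gaussian used to smooth the
#'   ball-and-stick scene (21x21, sigma 21)
#' @param final_blur_size,final_blur_sigma small blending blur applied after
#'   noise addition
#' @param noise a `noise_config`
#' @return a `render_config`
#' @export
render_config <- function(soma_semiaxis_um_range = c(4, 26), noise_floor = 10,
                          scene_blur_size = 21L, scene_blur_sigma = 21,
                          final_blur_size = 3L, final_blur_sigma = 1,
                          noise = noise_config()) {
  if (any(soma_semiaxis_um_range <= 0) || diff(soma_semiaxis_um_range) < 0)
    stop("invalid soma semi-axis range")
  structure(list(soma_semiaxis_um_range = soma_semiaxis_um_range,
                 noise_floor = noise_floor,
                 scene_blur_size = as.integer(scene_blur_size),
                 scene_blur_sigma = scene_blur_sigma,
                 final_blur_size = as.integer(final_blur_size),
                 final_blur_sigma = final_blur_sigma, noise = noise),
            class = "render_config")
}

#' Soma shape
#'
#' A cell body is the non-negative cap `z = r^2 - (a x^2 + b y^2)` (zero
#' where the quadratic form reaches `r^2`), rotated by `theta`.  `a` and
#' `b` are inverse squared semi-axes, so the soma extends `r / sqrt(a)`
#' micrometers along its rotated x axis.
#'
#' @param center length-2 numeric, center in micrometers
#' @param a,b positive x/y scale factors
#' @param theta_deg rotation angle in degrees (1--360)
#' @param r cap radius parameter (fixed 1 in the rendering pipeline)
#' @return a `soma_shape`
#' @export
soma_shape <- function(center, a, b, theta_deg = 0, r = 1) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  structure(list(center = as.numeric(center), a = a, b = b,
                 theta_deg = theta_deg, r = r), class = "soma_shape")
}

#' Sample soma shapes for a dish
#'
#' One ellipsoid per soma center; per-axis semi-extents are drawn uniformly
#' over `cfg$soma_semiaxis_um_range` and the rotation uniformly in
#' (1, 360) degrees.
#'
#' @param timeline a `dish_timeline`
#' @param cfg a `render_config`
#' @param seed integer seed
#' @return list of `soma_shape`
#' @export
sample_somata <- function(timeline, cfg = render_config(), seed = 1L) {
  set.seed(seed)
  rng <- cfg$soma_semiaxis_um_range
  lapply(seq_len(nrow(timeline$soma_centers)), function(i) {
    sx <- stats::runif(1, rng[1], rng[2])
    sy <- stats::runif(1, rng[1], rng[2])
    th <- stats::runif(1, 1, 360)
    soma_shape(timeline$soma_centers[i, ], a = 1 / sx^2, b = 1 / sy^2,
               theta_deg = th, r = 1)
  })
}

#' Evaluate a soma height profile on a pixel grid
#'
#' Evaluates the rotated cap profile at every pixel center of a
#' `grid_px` x `grid_px` raster with the given pitch.  The profile is
#' `r^2 - (a x'^2 + b y'^2)` where (x', y') are coordinates (in um)
#' relative to the center after rotating by `theta`, and 0 outside the
#' support.
#'
#' @param shape a `soma_shape`
#' @param grid_px raster side in pixels
#' @param pitch_um pixel pitch in micrometers
#' @return numeric matrix (grid x grid), non-negative, `r^2` at the center
#' @export
soma_profile <- function(shape, grid_px, pitch_um) {
  if (shape$a <= 0 || shape$b <= 0) stop("a and b must be positive")
  cx <- (seq_len(grid_px) - 0.5) * pitch_um   # pixel-center coordinates
  dx <- outer(rep(1, grid_px), cx - shape$center[1])  # row = y, col = x
  dy <- outer(cx - shape$center[2], rep(1, grid_px))
  th <- shape$theta_deg * pi / 180
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  q <- shape$a * xr^2 + shape$b * yr^2
  z <- shape$r^2 - q
  z[q >= shape$r^2] <- 0
  z
}

#' Compose the ball-and-stick scene
#'
#' Sums all soma profiles into a zero field (overlapping cells add, which
#' brightens crowded regions as in real phase images), normalizes the soma
#' field by its maximum onto 0--255 to avoid clipping, then writes the
#' 255-valued 1-pixel neurite lines on top.
#'
#' @param somata list of `soma_shape` (may be empty)
#' @param skeleton raster from [rasterize_skeleton()]
#' @param pitch_um pixel pitch in micrometers
#' @return list with `scene` (somata + neurites) and `soma_field` (somata
#'   only, 0--255), both grid-sized numeric matrices
#' @export
compose_scene <- function(somata, skeleton, pitch_um) {
  g <- nrow(skeleton)
  field <- matrix(0, g, g)
  for (s in somata) field <- field + soma_profile(s, g, pitch_um)
  if (max(field) > 0) field <- field / max(field) * 255
  scene <- field
  scene[skeleton > 0] <- 255
  list(scene = scene, soma_field = field)
}

#' Smooth a scene into a phase-like profile
#'
#' Gaussian blur (default 21x21, sigma 21 px on both axes).  This rounds
#' the somata into dome-like phase profiles and leaves thin neurites with
#' low signal relative to the cell body, as in real QPI.
#'
#' @param scene numeric matrix
#' @param size,sigma kernel size and SD in pixels
#' @return blurred matrix
#' @export
smooth_scene <- function(scene, size = 21L, sigma = 21) {
  blur_gaussian(scene, size, sigma)
}

#' Synthesize speckle/debris noise
#'
#' Uniform field thresholded at `cfg$seed_threshold` (about 5% of pixels
#' set to 255 with the default), then blurred sequentially with the
#' configured Gaussian cascade (3x3, 11x11, 31x31 by default).  A fresh
#' sample should be drawn for every rendered image.
#'
#' @param grid_px raster side in pixels
#' @param cfg a `noise_config`
#' @param seed integer seed
#' @return non-negative numeric matrix; attribute `pre_blur_high_frac`
#'   records the fraction of seed pixels before blurring
#' @export
synth_noise <- function(grid_px, cfg = noise_config(), seed = 1L) {
  set.seed(seed)
  u <- matrix(stats::runif(grid_px^2), grid_px, grid_px)
  m <- matrix(0, grid_px, grid_px)
  m[u > cfg$seed_threshold] <- cfg$high_value
  frac <- mean(m > 0)
  for (i in seq_along(cfg$blur_kernel_sizes))
    m <- blur_gaussian(m, cfg$blur_kernel_sizes[i], cfg$blur_sigmas[i])
  attr(m, "pre_blur_high_frac") <- frac
  m
}

#' Finalize a rendered image
#'
#' Adds the noise to the blurred scene, applies a small blending blur,
#' max-normalizes to 0--255 and quantizes to 8 bits (floor).
#'
#' @param blurred blurred scene matrix
#' @param noise noise matrix of the same dimensions
#' @param pitch_um pixel pitch carried into the output
#' @param final_blur_size,final_blur_sigma blending blur parameters
#' @return a uint8 `phase_image`
#' @export
finalize_image <- function(blurred, noise, pitch_um = 0.69,
                           final_blur_size = 3L, final_blur_sigma = 1) {
  if (!all(dim(blurred) == dim(noise))) stop("scene/noise shape mismatch")
  out <- blur_gaussian(blurred + noise, final_blur_size, final_blur_sigma)
  mx <- max(out)
  out <- if (mx > 0) pmin(floor(out / mx * 255), 255) else out * 0
  phase_image(out, pixel_pitch_um = pitch_um, units = "uint8")
}

#' Automatic three-class labels for a rendered scene
#'
#' Cell body wherever the smoothed soma-only field exceeds the noise
#' floor; neurite wherever the skeleton mask is set and not already cell
#' body (cell body takes precedence where somata cover neurites);
#' background elsewhere.
#'
#' @param soma_field_smoothed smoothed soma-only field (0--255 scale)
#' @param skeleton_mask logical neurite mask from [rasterize_skeleton()]
#' @param noise_floor cell-body threshold on the 0--255 scale
#' @param pitch_um pixel pitch carried into the output
#' @return a `label_image`
#' @export
make_labels <- function(soma_field_smoothed, skeleton_mask, noise_floor = 10,
                        pitch_um = 0.69) {
  body <- soma_field_smoothed > noise_floor
  cl <- matrix(LBL_BACKGROUND, nrow(body), ncol(body))
  cl[skeleton_mask] <- LBL_NEURITE
  cl[body] <- LBL_BODY
  label_image(cl, pixel_pitch_um = pitch_um)
}

#' Render one image/label pair from a dish timeline
#'
#' Full rendering pipeline for the state of a dish at one time step:
#' skeleton rasterization, soma sampling (fixed per dish so cells keep
#' their size across time steps), scene composition, smoothing, per-image
#' noise, finalization and automatic labeling.
#'
#' @param timeline a `dish_timeline`
#' @param step_index time step to render
#' @param cfg a `render_config`
#' @param seed integer seed; soma shapes derive from (seed, "somata") and
#'   noise from (seed, "noise<step>") so each step gets fresh noise
#' @return list with `image` (uint8 `phase_image`), `label`
#'   (`label_image`) and `skeleton`
#' @export
render_dish <- function(timeline, step_index = timeline$step,
                        cfg = render_config(), seed = 1L) {
  gcfg <- timeline$config
  pitch <- pixel_pitch(gcfg)
  skel <- rasterize_skeleton(timeline, step_index)
  somata <- sample_somata(timeline, cfg, seed = derive_seed(seed, "somata"))
  comp <- compose_scene(somata, skel, pitch)
  blurred <- smooth_scene(comp$scene, cfg$scene_blur_size, cfg$scene_blur_sigma)
  soma_smooth <- smooth_scene(comp$soma_field, cfg$scene_blur_size, cfg$scene_blur_sigma)
  noise <- synth_noise(gcfg$grid_px, cfg$noise,
                       seed = derive_seed(seed, paste0("noise", step_index)))
  img <- finalize_image(blurred, noise, pitch_um = pitch,
                        final_blur_size = cfg$final_blur_size,
                        final_blur_sigma = cfg$final_blur_sigma)
  lab <- make_labels(soma_smooth, attr(skel, "mask"), cfg$noise_floor, pitch)
  list(image = img, label = lab, skeleton = skel)
}
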