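# Stochastic 2-D neurite outgrowth engine.  Each simulated "Petri dish" is a
# field of view seeded with somata; growth cones elongate, turn and branch
# once per time step, leaving behind 1-pixel-wide line segments that later
# become the neurite skeleton of a pseudo-QPI image.

#' Growth simulation configuration
#'
#' Parameters of the per-step stochastic rules.  At every step each active
#' growth cone (a) elongates by a clamped-normal draw
#' `max(0, N(elongation_mean_um, elongation_sd_um))` along its heading,
#' (b) turns by `N(0, turn_sd_rad)`, and (c) branches with probability
#' `branch_base_prob * 2^(-branch_order_sensitivity * order)`, where order
#' is the cone's centrifugal order (branch points between it and the soma).
#' Branching replaces the cone with two cones of order + 1 whose headings
#' are offset symmetrically by `branch_half_angle_rad`.
#'
#' Defaults are calibrated so that a default 512-grid, 25-step dish
#' population puts rasterized neurite pixels at roughly 3--8% of the image
#' area, matching the neurite share observed in real ground-truth masks.
#'
#' @param field_size_um side of the square field of view (default 353.28 um,
#'   i.e. 512 px at 0.69 um)
#' @param grid_px raster grid side in pixels
#' @param n_steps number of growth steps
#' @param n_neurons_min,n_neurons_max bounds of the uniform neuron count
#' @param initial_neurites_min,initial_neurites_max bounds of the uniform
#'   number of initial neurites (stems) per neuron
#' @param elongation_mean_um,elongation_sd_um per-step elongation draw (um)
#' @param branch_base_prob per-cone per-step branching probability at order 0
#' @param branch_order_sensitivity order damping exponent (>= 0)
#' @param branch_half_angle_rad half-angle between daughter headings
#' @param turn_sd_rad per-step heading perturbation SD
#' @param seed default seed used by [simulate_dish()]
#' @return a `growth_config` list
#' @export
growth_config <- function(field_size_um = 353.28, grid_px = 512L, n_steps = 25L,
                          n_neurons_min = 1L, n_neurons_max = 10L,
                          initial_neurites_min = 2L, initial_neurites_max = 5L,
                          elongation_mean_um = 14, elongation_sd_um = 4,
                          branch_base_prob = 0.25, branch_order_sensitivity = 1,
                          branch_half_angle_rad = pi / 6, turn_sd_rad = 0.35,
                          seed = 1L) {
  cfg <- list(field_size_um = field_size_um, grid_px = as.integer(grid_px),
              n_steps = as.integer(n_steps),
              n_neurons_min = as.integer(n_neurons_min),
              n_neurons_max = as.integer(n_neurons_max),
              initial_neurites_min = as.integer(initial_neurites_min),
              initial_neurites_max = as.integer(initial_neurites_max),
              elongation_mean_um = elongation_mean_um,
              elongation_sd_um = elongation_sd_um,
              branch_base_prob = branch_base_prob,
              branch_order_sensitivity = branch_order_sensitivity,
              branch_half_angle_rad = branch_half_angle_rad,
              turn_sd_rad = turn_sd_rad, seed = as.integer(seed))
  validate_growth_config(cfg)
  structure(cfg, class = "growth_config")
}

validate_growth_config <- function(cfg) {
  with(cfg, {
    if (field_size_um <= 0 || grid_px < 1) stop("invalid field/grid")
    if (n_steps < 0) stop("n_steps must be >= 0")
    if (!(1 <= n_neurons_min && n_neurons_min <= n_neurons_max))
      stop("need 1 <= n_neurons_min <= n_neurons_max")
    if (initial_neurites_min < 1 || initial_neurites_min > initial_neurites_max)
      stop("invalid initial neurite range")
    if (elongation_mean_um < 0 || elongation_sd_um < 0 || turn_sd_rad < 0)
      stop("rate/sigma parameters must be >= 0")
    if (branch_base_prob < 0 || branch_base_prob > 1)
      stop("branch_base_prob must be in [0, 1]")
    if (branch_order_sensitivity < 0)
      stop("branch_order_sensitivity must be >= 0")
  })
  invisible(cfg)
}

#' Physical pixel pitch of a growth configuration
#' @param config a `growth_config`
#' @return pitch in micrometers (field size / grid)
#' @export
pixel_pitch <- function(config) config$field_size_um / config$grid_px

empty_segments <- function() {
  data.frame(neuron_id = integer(), order = integer(), birth_step = integer(),
             x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric())
}

#' Initialize a simulated Petri dish
#'
#' Draws the neuron count uniformly in
#' `[n_neurons_min, n_neurons_max]`, places soma centers uniformly in the
#' field, and seeds each neuron with its initial growth cones at
#' centrifugal order 0.  Stem headings are evenly spaced around the circle
#' with a random common rotation and small per-cone jitter.  The timeline
#' starts at step 0 with no segments.
#'
#' Random draws are consumed in a fixed order (neuron count, soma
#' placement, then per-neuron stem configuration), so identical
#' (config, seed) pairs give identical timelines.
#'
#' @param config a `growth_config`
#' @param seed integer seed (defaults to `config$seed`)
#' @return a `dish_timeline`
#' @export
init_dish <- function(config, seed = config$seed) {
  validate_growth_config(config)
  set.seed(seed)
  n <- if (config$n_neurons_min == config$n_neurons_max) config$n_neurons_min
       else sample(config$n_neurons_min:config$n_neurons_max, 1L)
  centers <- cbind(x = stats::runif(n, 0, config$field_size_um),
                   y = stats::runif(n, 0, config$field_size_um))
  cones <- NULL
  for (id in seq_len(n)) {
    k <- if (config$initial_neurites_min == config$initial_neurites_max)
           config$initial_neurites_min
         else sample(config$initial_neurites_min:config$initial_neurites_max, 1L)
    base <- stats::runif(1, 0, 2 * pi)
    jit <- stats::rnorm(k, 0, 0.15)
    cones <- rbind(cones, data.frame(
      x = unname(centers[id, 1]), y = unname(centers[id, 2]),
      heading = base + 2 * pi * (seq_len(k) - 1) / k + jit,
      order = 0L, neuron_id = id, active = TRUE))
  }
  structure(list(soma_centers = centers, segments = empty_segments(),
                 cones = cones, config = config, step = 0L, seed = seed),
            class = "dish_timeline")
}

#' @export
print.dish_timeline <- function(x, ...) {
  cat(sprintf("<dish_timeline: %d neurons, step %d/%d, %d segments, %d active cones>\n",
              nrow(x$soma_centers), x$step, x$config$n_steps,
              nrow(x$segments), sum(x$cones$active)))
  invisible(x)
}

# clip the segment (p0 -> p1) to the square [0, L]^2; returns the clipped
# end point, or NULL if p0 itself is outside (should not happen: cones are
# deactivated as soon as they touch the boundary)
clip_to_field <- function(p0, p1, L) {
  d <- p1 - p0
  tmax <- 1
  for (k in 1:2) {
    if (d[k] > 0) tmax <- min(tmax, (L - p0[k]) / d[k])
    else if (d[k] < 0) tmax <- min(tmax, (0 - p0[k]) / d[k])
  }
  p0 + max(0, tmax) * d
}

#' Advance all growth cones by one time step
#'
#' Applies elongation, turning and branching (in that per-cone order) to
#' every active cone.  Cones whose elongation would leave the field have
#' their segment clipped to the boundary and are deactivated.  Uses the
#' current R random stream; [simulate_dish()] seeds it once per dish.
#'
#' @param timeline a `dish_timeline`
#' @param step_index step number being executed, in `[1, n_steps]`
#' @return updated `dish_timeline`
#' @export
step_cones <- function(timeline, step_index) {
  cfg <- timeline$config
  if (step_index < 1 || step_index > cfg$n_steps)
    stop("step_index must be in [1, n_steps]")
  L <- cfg$field_size_um
  cones <- timeline$cones
  segs <- vector("list", nrow(cones))
  out <- vector("list", nrow(cones))
  for (i in seq_len(nrow(cones))) {
    cn <- cones[i, ]
    if (!cn$active) { out[[i]] <- cn; next }
    # (a) elongation
    len <- max(0, stats::rnorm(1, cfg$elongation_mean_um, cfg$elongation_sd_um))
    p0 <- c(cn$x, cn$y)
    p1 <- p0 + len * c(cos(cn$heading), sin(cn$heading))
    left_field <- any(p1 < 0 | p1 > L)
    if (left_field) p1 <- clip_to_field(p0, p1, L)
    segs[[i]] <- data.frame(neuron_id = cn$neuron_id, order = cn$order,
                            birth_step = step_index,
                            x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2])
    cn$x <- p1[1]; cn$y <- p1[2]
    if (left_field) { cn$active <- FALSE; out[[i]] <- cn; next }
    # (b) turning
    cn$heading <- cn$heading + stats::rnorm(1, 0, cfg$turn_sd_rad)
    # (c) branching, damped by centrifugal order (0 * Inf reads as no damping)
    damp_exp <- cfg$branch_order_sensitivity * cn$order
    if (is.nan(damp_exp)) damp_exp <- 0
    pbr <- cfg$branch_base_prob * 2^(-damp_exp)
    if (stats::runif(1) < pbr) {
      half <- cfg$branch_half_angle_rad
      out[[i]] <- rbind(
        transform(cn, heading = heading - half, order = order + 1L),
        transform(cn, heading = heading + half, order = order + 1L))
    } else out[[i]] <- cn
  }
  timeline$cones <- do.call(rbind, out)
  new_segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (!is.null(new_segs)) timeline$segments <- rbind(timeline$segments, new_segs)
  timeline$step <- step_index
  timeline
}

#' Simulate a full Petri dish
#'
#' Runs [init_dish()] followed by `n_steps` calls to [step_cones()].  The
#' returned timeline carries every segment with its birth step, so the
#' cumulative state at any step is recoverable with [segments_at_step()].
#'
#' @param config a `growth_config`
#' @param seed integer seed (defaults to `config$seed`)
#' @return a `dish_timeline` advanced to `n_steps`
#' @export
simulate_dish <- function(config, seed = config$seed) {
  tl <- init_dish(config, seed)
  for (s in seq_len(config$n_steps)) tl <- step_cones(tl, s)
  tl
}

#' Cumulative segment table at a given step
#' @param timeline a `dish_timeline`
#' @param step_index step (0 = before any growth)
#' @return data frame of segments with `birth_step <= step_index`
#' @export
segments_at_step <- function(timeline, step_index) {
  timeline$segments[timeline$segments$birth_step <= step_index, , drop = FALSE]
}

# continuous um position -> 1-based pixel index under the half-open cell
# convention: pixel k covers [ (k-1)*pitch, k*pitch )
um_to_px <- function(p, pitch, grid) clamp(floor(p / pitch) + 1L, 1L, grid)

#' Rasterize the neurite skeleton at a time step
#'
#' Draws every segment alive at `step_index` as a 1-pixel-wide Bresenham
#' line of intensity 255 on the configured grid.  Pixel (1,1) is the
#' top-left corner; position p um maps to pixel `floor(p / pitch) + 1` with
#' pitch = field_size_um / grid_px.
#'
#' @param timeline a `dish_timeline`
#' @param step_index time step to rasterize (defaults to the current step)
#' @return integer matrix (grid x grid) with values 0/255; attribute `mask`
#'   holds the logical neurite mask used for labeling
#' @export
rasterize_skeleton <- function(timeline, step_index = timeline$step) {
  cfg <- timeline$config
  g <- cfg$grid_px
  pitch <- pixel_pitch(cfg)
  ras <- matrix(0L, g, g)
  segs <- segments_at_step(timeline, step_index)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    pts <- bresenham(um_to_px(s$x0, pitch, g), um_to_px(s$y0, pitch, g),
                     um_to_px(s$x1, pitch, g), um_to_px(s$y1, pitch, g))
    ras[cbind(pts[, "y"], pts[, "x"])] <- 255L  # row = y, col = x
  }
  attr(ras, "mask") <- ras > 0L
  ras
}

#' Total neurite path length at a step
#' @param timeline a `dish_timeline`
#' @param step_index time step
#' @return total segment length in micrometers
#' @export
total_path_length <- function(timeline, step_index = timeline$step) {
  s <- segments_at_step(timeline, step_index)
  if (!nrow(s)) return(0)
  sum(sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2))
}

#' Write / read a segment table as CSV
#'
#' One row per segment: neuron_id, order, birth_step, x0, y0, x1, y1 (um).
#' @param timeline a `dish_timeline`
#' @param path output CSV path
#' @export
write_segments_csv <- function(timeline, path) {
  utils::write.csv(timeline$segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @param config the `growth_config` the segments were generated under
#' @export
read_segments_csv <- function(path, config) {
  segs <- utils::read.csv(path)
  need <- c("neuron_id", "order", "birth_step", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(segs))) stop("not a segment table: ", path)
  structure(list(soma_centers = unique(as.matrix(
                   segs[segs$order == 0 & segs$birth_step == 1, c("x0", "y0")])),
                 segments = segs, cones = NULL, config = config,
                 step = max(c(0L, segs$birth_step)), seed = NA_integer_),
            class = "dish_timeline")
}
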