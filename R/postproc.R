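# Post-processing of segmentation masks and phase maps: connected-region
# size filtering with a Dice-optimal threshold sweep, the Dice evaluation
# suite, dry-mass quantification, and cell-extent measurement.

#' Region size filter configuration
#'
#' @param min_area_um2 regions smaller than this are removed (default 714)
#' @param sweep_range candidate thresholds for [select_area_threshold()]
#'   (default 119 to 1071 in steps of 119)
#' @param connectivity 8 (default) or 4
#' @param pixel_pitch_um fallback pixel pitch when a label carries none
#' @return a `region_filter_config`
#' @export
region_filter_config <- function(min_area_um2 = 714,
                                 sweep_range = seq(119, 1071, by = 119),
                                 connectivity = 8, pixel_pitch_um = 0.69) {
  if (min_area_um2 < 0) stop("min_area_um2 must be >= 0")
  if (any(diff(sweep_range) <= 0) || any(sweep_range <= 0))
    stop("sweep values must be positive and increasing")
  structure(list(min_area_um2 = min_area_um2, sweep_range = sweep_range,
                 connectivity = connectivity, pixel_pitch_um = pixel_pitch_um),
            class = "region_filter_config")
}

label_pitch <- function(label, cfg) {
  attr(label, "pixel_pitch_um") %||% cfg$pixel_pitch_um
}

#' Remove small connected regions from a label
#'
#' Binarizes the label (any non-background class = foreground), finds
#' connected regions, computes each region's physical area (pixel count
#' times pitch squared) and resets every pixel of regions smaller than
#' `cfg$min_area_um2` to background.  Surviving pixels keep their class.
#'
#' @param label a `label_image`
#' @param cfg a `region_filter_config` (or a numeric area threshold)
#' @return filtered `label_image`
#' @export
size_filter <- function(label, cfg = region_filter_config()) {
  if (is.numeric(cfg)) cfg <- region_filter_config(min_area_um2 = cfg)
  pitch <- label_pitch(label, cfg)
  lab <- label_regions(unclass(label) > 0L, cfg$connectivity)
  if (max(lab) == 0L) return(label)
  areas <- tabulate(lab[lab > 0L]) * pitch^2
  drop <- which(areas < cfg$min_area_um2)
  out <- unclass(label)
  out[lab %in% drop] <- LBL_BACKGROUND
  label_image(out, pixel_pitch_um = pitch)
}

#' Select the Dice-optimal area threshold
#'
#' Size-filters every prediction at each candidate threshold in
#' `cfg$sweep_range` and scores the filtered set against the ground truths
#' with the overall three-channel Dice coefficient (flattened across all
#' images).  Returns the threshold with the highest Dice; exact ties go to
#' the smallest (least destructive) threshold.
#'
#' @param predictions list of predicted `label_image`s
#' @param truths list of matching ground-truth `label_image`s
#' @param cfg a `region_filter_config`
#' @return selected area threshold in square micrometers; the sweep table
#'   (threshold, dice) is attached as attribute `sweep`
#' @export
select_area_threshold <- function(predictions, truths,
                                  cfg = region_filter_config()) {
  if (!length(predictions) || length(predictions) != length(truths))
    stop("need matched, non-empty prediction/truth lists")
  scores <- vapply(cfg$sweep_range, function(thr) {
    c2 <- cfg; c2$min_area_um2 <- thr
    t_all <- p_all <- vector("list", length(predictions))
    for (i in seq_along(predictions)) {
      p_all[[i]] <- label_onehot(size_filter(predictions[[i]], c2))
      t_all[[i]] <- label_onehot(truths[[i]])
    }
    dice_coefficient(do.call(rbind, t_all), do.call(rbind, p_all))
  }, numeric(1))
  best <- cfg$sweep_range[which.max(scores)]   # which.max takes the first tie
  attr(best, "sweep") <- data.frame(threshold = cfg$sweep_range, dice = scores)
  best
}

#' Dice evaluation suite
#'
#' Four granularities of agreement between a predicted and a true label:
#' whole-cell (any cell class vs. background), three-channel (flattened
#' one-hot stacks), cell body only, and neurite only.
#'
#' @param pred,truth `label_image`s with identical dimensions
#' @return named numeric vector:
#'   `cell_vs_not`, `three_channel`, `cell_body`, `neurite`
#' @export
evaluate_dice_suite <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("prediction/truth shape mismatch")
  p <- unclass(pred); t <- unclass(truth)
  c(cell_vs_not = dice_coefficient(t > 0L, p > 0L),
    three_channel = dice_coefficient(label_onehot(t), label_onehot(p)),
    cell_body = dice_coefficient(t == LBL_BODY, p == LBL_BODY),
    neurite = dice_coefficient(t == LBL_NEURITE, p == LBL_NEURITE))
}

#' Cellular dry mass from a phase map
#'
#' `m = lambda / (2 pi alpha) * sum(phase over mask) * pitch^2`, the
#' integral of phase over the masked region scaled by the specific
#' refraction increment.  With lambda in micrometers, alpha in cubic
#' micrometers per picogram, phase in radians and pitch in micrometers,
#' the result is in picograms.
#'
#' @param phase `phase_image` in radians (plain matrices accepted)
#' @param mask logical matrix of the same dimensions
#' @param wavelength_um illumination wavelength (default 0.6328 um)
#' @param alpha specific refraction increment (default 0.2 um^3/pg,
#'   i.e. 0.2 ml/g)
#' @param pitch_um pixel pitch; defaults to the phase image's pitch or
#'   0.345 um (the 1024-grid pitch used for mass quantification)
#' @return dry mass in picograms
#' @export
dry_mass <- function(phase, mask, wavelength_um = 0.6328, alpha = 0.2,
                     pitch_um = attr(phase, "pixel_pitch_um") %||% 0.345) {
  if (wavelength_um <= 0 || alpha <= 0) stop("wavelength and alpha must be positive")
  if (!all(dim(phase) == dim(mask))) stop("phase/mask shape mismatch")
  wavelength_um / (2 * pi * alpha) * sum(unclass(phase)[mask]) * pitch_um^2
}

#' Upsample a binary mask or label raster (nearest neighbour)
#'
#' Used to carry 512-grid masks onto the 1024-grid phase maps before mass
#' integration; nearest-neighbour resampling preserves binarity/classes.
#'
#' @param mask logical/integer matrix
#' @param target output side in pixels (default 1024)
#' @return resampled matrix of the same type
#' @export
upsample_mask <- function(mask, target = 1024L) {
  out <- resize_matrix(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       target, target, method = "nearest")
  if (is.logical(mask)) out > 0.5 else matrix(as.integer(round(out)), target, target)
}

#' Dry-mass percent differences between predicted and true labels
#'
#' Computes dry mass over the whole-cell (body plus neurite), body-only
#' and neurite-only masks of both labels, and the absolute percent
#' difference of each compartment relative to the ground truth.  Labels
#' whose grid differs from the phase map are upsampled to it with nearest
#' neighbour first.  A compartment with zero true mass has an undefined
#' percent difference, reported as NA.
#'
#' @param pred_label,true_label `label_image`s
#' @param phase `phase_image` in radians
#' @param ... passed to [dry_mass()]
#' @return a `dry_mass_result`: data frame with one row per compartment
#'   (whole, cell_body, neurite) and columns mass_pred_pg, mass_true_pg,
#'   pct_diff
#' @export
percent_diff_mass <- function(pred_label, true_label, phase, ...) {
  g <- nrow(phase)
  align <- function(l) {
    m <- unclass(l)
    if (nrow(m) != g) m <- upsample_mask(m, g)
    m
  }
  p <- align(pred_label); t <- align(true_label)
  comp <- list(whole = function(m) m > 0L,
               cell_body = function(m) m == LBL_BODY,
               neurite = function(m) m == LBL_NEURITE)
  res <- lapply(names(comp), function(nm) {
    mp <- dry_mass(phase, comp[[nm]](p), ...)
    mt <- dry_mass(phase, comp[[nm]](t), ...)
    data.frame(compartment = nm, mass_pred_pg = mp, mass_true_pg = mt,
               pct_diff = if (mt > 0) abs(mp - mt) / mt * 100 else NA_real_)
  })
  structure(do.call(rbind, res), class = c("dry_mass_result", "data.frame"))
}

#' Aggregate dry-mass percent differences over an image set
#'
#' @param results list of `dry_mass_result`s (one per image)
#' @return data frame per compartment: mean percent difference, standard
#'   error of the mean (sd / sqrt(N)), and N
#' @export
aggregate_mass_diff <- function(results) {
  all <- do.call(rbind, results)
  out <- do.call(rbind, lapply(split(all, all$compartment), function(d) {
    x <- d$pct_diff[!is.na(d$pct_diff)]
    data.frame(compartment = d$compartment[1], mean_pct_diff = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  }))
  rownames(out) <- NULL
  out[match(c("whole", "cell_body", "neurite"), out$compartment), ]
}

#' Convert a phase map in radians to a uint8 image
#'
#' Negative phase (background noise after background subtraction) is
#' clipped to zero; the minimum is subtracted, the result divided by its
#' maximum, scaled to 0--255 and floor-quantized.  An image that is
#' all-zero after clipping is returned as all zeros.
#'
#' @param phase `phase_image` in radians
#' @return uint8 `phase_image`
#' @export
qpi_to_uint8 <- function(phase) {
  x <- pmax(unclass(phase), 0)
  x <- x - min(x)
  mx <- max(x)
  out <- if (mx > 0) floor(x / mx * 255) else x
  phase_image(out, pixel_pitch_um = attr(phase, "pixel_pitch_um") %||% 0.345,
              units = "uint8")
}

#' Per-cell bounding boxes and axis lengths
#'
#' Finds connected regions of the cell-body class and reports each
#' region's rectangular bounding box and its axis lengths in micrometers.
#'
#' @param label a `label_image`
#' @param pitch_um pixel pitch (defaults to the label's)
#' @param connectivity 8 (default) or 4
#' @return data frame: region, row/col bounds, extent_x_um, extent_y_um,
#'   major_um, minor_um, area_um2 (empty when no cell bodies exist)
#' @export
cell_extents <- function(label, pitch_um = attr(label, "pixel_pitch_um") %||% 0.69,
                         connectivity = 8) {
  lab <- label_regions(unclass(label) == LBL_BODY, connectivity)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(region = integer(), row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer(),
                      extent_x_um = numeric(), extent_y_um = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      area_um2 = numeric()))
  do.call(rbind, lapply(seq_len(n), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    ex <- (diff(range(w[, 2])) + 1) * pitch_um   # x = columns
    ey <- (diff(range(w[, 1])) + 1) * pitch_um
    data.frame(region = k, row_min = min(w[, 1]), row_max = max(w[, 1]),
               col_min = min(w[, 2]), col_max = max(w[, 2]),
               extent_x_um = ex, extent_y_um = ey,
               major_um = max(ex, ey), minor_um = min(ex, ey),
               area_um2 = nrow(w) * pitch_um^2)
  }))
}
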