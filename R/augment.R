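# Augmentation policy: random rescale (clamped normal), 4-way flip, 4-way
# right-angle rotation, and gamma scaling of the image only.  Geometric
# transforms are applied identically to image and label so pairs keep
# their 1-to-1 relationship.

#' Sample one realization of the augmentation policy
#'
#' Draws, in a fixed order: scale ~ N(1, 0.25) clipped to \[0.5, 1.5\];
#' flip uniform over \{none, lr, ud, lr+ud\}; rotation uniform over
#' \{0, 90, 180, 270\} degrees; gamma ~ N(1, 0.35) clipped to \[0.7, 1.7\];
#' and two uniforms that position the crop window used when scale < 1.
#'
#' @param clip if `TRUE` (default) out-of-range normals are clamped to the
#'   bounds; if `FALSE` they are rejection-sampled inside them
#' @return an `augment_params` list
#' @export
sample_augment_params <- function(clip = TRUE) {
  draw <- function(mu, sd, lo, hi) {
    if (clip) return(clamp(stats::rnorm(1, mu, sd), lo, hi))
    repeat { x <- stats::rnorm(1, mu, sd); if (x >= lo && x <= hi) return(x) }
  }
  scale <- draw(1, 0.25, 0.5, 1.5)
  flip <- sample(c("none", "lr", "ud", "lrud"), 1)
  rotation <- sample(c(0L, 90L, 180L, 270L), 1)
  gamma <- draw(1, 0.35, 0.7, 1.7)
  crop_u <- stats::runif(2)
  structure(list(scale = scale, flip = flip, rotation = rotation,
                 gamma = gamma, crop_u = crop_u), class = "augment_params")
}

flip_mat <- function(m, flip) {
  switch(flip,
         none = m,
         lr = m[, ncol(m):1, drop = FALSE],
         ud = m[nrow(m):1, , drop = FALSE],
         lrud = m[nrow(m):1, ncol(m):1, drop = FALSE],
         stop("unknown flip option: ", flip))
}

rot90_mat <- function(m, deg) {
  switch(as.character(deg %% 360L),
         "0" = m,
         "90" = t(m)[nrow(m):1, , drop = FALSE][, , drop = FALSE],
         "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
         "270" = t(m)[, ncol(m):1, drop = FALSE],
         stop("rotation must be a multiple of 90 degrees"))
}

rescale_mat <- function(m, params, method) {
  n <- nrow(m)
  s <- params$scale
  if (abs(s - 1) < 1e-12) return(m)
  if (s > 1) {                       # pad then shrink: content appears smaller
    target <- round(n * s)
    padded <- matrix(0, target, target)
    off <- floor((target - n) / 2)
    padded[off + seq_len(n), off + seq_len(n)] <- m
    resize_matrix(padded, n, n, method = method)
  } else {                           # crop then enlarge: content appears larger
    cs <- max(1L, round(n * s))
    r0 <- floor(params$crop_u[1] * (n - cs)) + 1L
    c0 <- floor(params$crop_u[2] * (n - cs)) + 1L
    resize_matrix(m[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L), drop = FALSE],
                  n, n, method = method)
  }
}

#' Apply augmentation parameters to an image/label pair
#'
#' Rescaling (zero-pad + shrink for scale > 1, random crop + enlarge for
#' scale < 1), flip and rotation are applied identically to image and
#' label; the label is resampled with nearest-neighbour interpolation so
#' classes stay crisp.  Gamma is applied to the image only: the image is
#' normalized to \[0, 1\], raised to the power `gamma`, and mapped back to
#' its original scale.
#'
#' @param image a uint8 or normalized `phase_image` (square)
#' @param label the matching `label_image`
#' @param params an `augment_params`
#' @return list with transformed `image` and `label`
#' @export
apply_augment <- function(image, label, params) {
  if (!all(dim(image) == dim(label))) stop("image/label dimension mismatch")
  if (nrow(image) != ncol(image)) stop("augmentation expects square rasters")
  units <- attr(image, "units") %||% "uint8"
  pitch <- attr(image, "pixel_pitch_um") %||% 0.69
  top <- if (units == "uint8") 255 else 1

  img <- unclass(image)
  img <- rescale_mat(img, params, "bilinear")
  img <- flip_mat(img, params$flip)
  img <- rot90_mat(img, params$rotation)
  img01 <- clamp(img / top, 0, 1)
  img01 <- img01^params$gamma
  img <- if (units == "uint8") floor(img01 * 255) else img01

  lab <- unclass(label)
  lab <- rescale_mat(lab, params, "nearest")
  lab <- flip_mat(lab, params$flip)
  lab <- rot90_mat(lab, params$rotation)

  list(image = phase_image(img, pitch, units),
       label = label_image(round(lab), pitch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an augmented dataset from a source pool
#'
#' Repeatedly picks a source pair uniformly at random, samples one
#' realization of the augmentation policy, and applies it; then uniformly
#' subsamples `n_subsample` of the `n_generate` generated pairs.  The
#' source pool may mix real and simulated pairs (e.g. 10 real + 90
#' simulated).
#'
#' @param sources non-empty list of `list(image =, label =)` pairs; an
#'   optional `source_id` element is carried into the manifest
#' @param n_generate number of augmented pairs to generate
#' @param n_subsample number of pairs retained (must be <= `n_generate`)
#' @param seed integer seed
#' @param out_dir if non-NULL, retained pairs are written there as PNG
#'   pairs (`img_%05d.png`, `lab_%05d.png`) instead of kept in memory
#' @return list with `pairs` (list of retained pairs, or file paths when
#'   `out_dir` is used) and `manifest` (data frame: output index, source
#'   index and id, sampled parameters)
#' @export
build_augmented_dataset <- function(sources, n_generate, n_subsample,
                                    seed = 1L, out_dir = NULL) {
  if (!length(sources)) stop("source list must be non-empty")
  if (n_subsample > n_generate) stop("n_subsample must be <= n_generate")
  set.seed(seed)
  src_idx <- sample.int(length(sources), n_generate, replace = TRUE)
  par_list <- replicate(n_generate, sample_augment_params(), simplify = FALSE)
  keep <- sort(sample.int(n_generate, n_subsample))
  pairs <- vector("list", n_subsample)
  for (k in seq_along(keep)) {
    i <- keep[k]
    src <- sources[[src_idx[i]]]
    out <- apply_augment(src$image, src$label, par_list[[i]])
    if (is.null(out_dir)) pairs[[k]] <- out
    else {
      ip <- file.path(out_dir, sprintf("img_%05d.png", k))
      lp <- file.path(out_dir, sprintf("lab_%05d.png", k))
      write_image_png(out$image, ip)
      write_label_png(out$label, lp)
      pairs[[k]] <- list(image = ip, label = lp)
    }
  }
  ids <- vapply(sources, function(s) s$source_id %||% NA_character_, character(1))
  manifest <- data.frame(
    out_index = seq_along(keep), gen_index = keep,
    source_index = src_idx[keep], source_id = ids[src_idx[keep]],
    scale = vapply(par_list[keep], `[[`, numeric(1), "scale"),
    flip = vapply(par_list[keep], `[[`, character(1), "flip"),
    rotation = vapply(par_list[keep], `[[`, integer(1), "rotation"),
    gamma = vapply(par_list[keep], `[[`, numeric(1), "gamma"))
  # source draws for the full generated set, for sampling diagnostics
  attr(manifest, "generated_source_index") <- src_idx
  list(pairs = pairs, manifest = manifest)
}
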