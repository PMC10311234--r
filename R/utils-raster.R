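# ---- small numeric helpers ------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Normalized 1-D Gaussian kernel
#'
#' @param size odd kernel length in pixels
#' @param sigma standard deviation in pixels
#' @return numeric vector of length `size` summing to 1
#' @keywords internal
gaussian_kernel1d <- function(size, sigma) {
  if (size %% 2 != 1 || size < 1) stop("kernel size must be odd and positive")
  if (sigma <= 0) stop("sigma must be positive")
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix for a centered 1-D kernel with zero padding at
# the borders.  Applying A %*% m %*% t(B) realizes a separable 2-D blur.
band_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1) / 2
  A <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) A[cbind(idx, idx + d)] <- kernel[d + half + 1]
    else A[cbind(idx - d, idx)] <- kernel[d + half + 1]
  }
  A
}

#' Separable Gaussian blur with zero-padded borders
#'
#' Blurs a 2-D raster with a `size` x `size` Gaussian of standard deviation
#' `sigma` (both axes).  Pixels outside the raster are treated as zero, and
#' the kernel is normalized to unit sum, so flat interior content is
#' preserved exactly and total intensity of content away from the borders is
#' conserved.
#'
#' @param m numeric matrix
#' @param size odd kernel size in pixels
#' @param sigma Gaussian standard deviation in pixels
#' @return blurred matrix of the same dimensions
#' @export
blur_gaussian <- function(m, size, sigma) {
  k <- gaussian_kernel1d(size, sigma)
  A <- band_matrix(nrow(m), k)
  B <- band_matrix(ncol(m), k)
  A %*% m %*% t(B)
}

# Summed-area-table box sum: value at (i,j) is the sum of `m` over the
# window of half-width `half` centered there, truncated at the borders.
box_sum <- function(m, half) {
  n <- nrow(m); p <- ncol(m)
  S <- matrix(0, n + 1, p + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i0 <- pmax(seq_len(n) - half - 1, 0); i1 <- pmin(seq_len(n) + half, n)
  j0 <- pmax(seq_len(p) - half - 1, 0); j1 <- pmin(seq_len(p) + half, p)
  S[i1 + 1, j1 + 1] - S[i0 + 1, j1 + 1] - S[i1 + 1, j0 + 1] + S[i0 + 1, j0 + 1]
}

#' Integer Bresenham line
#'
#' @param x0,y0,x1,y1 integer pixel coordinates
#' @return two-column integer matrix of (x, y) pixels on the 1-pixel-wide
#'   discrete line, endpoints included
#' @keywords internal
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

#' Label connected foreground regions
#'
#' Connected-component labeling of a logical/binary raster.  4-connected
#' components come from [EBImage::bwlabel()]; 8-connectivity is obtained by
#' merging 4-connected labels that touch diagonally (union-find over the
#' diagonal adjacency pairs).
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8 (default 8)
#' @return integer matrix; 0 = background, regions numbered from 1
#' @export
label_regions <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  if (connectivity == 8 && max(lab) > 1L) {
    n <- nrow(lab); p <- ncol(lab)
    a <- lab[-n, -p]; b <- lab[-1, -1]     # NW-SE diagonal neighbours
    c2 <- lab[-1, -p]; d <- lab[-n, -1]    # SW-NE
    pairs <- rbind(
      cbind(as.vector(a), as.vector(b)),
      cbind(as.vector(c2), as.vector(d)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      dense <- match(root, sort(unique(root)))
      lab[lab > 0] <- dense[lab[lab > 0]]
    }
  }
  lab
}

# nearest-neighbour / bilinear resize of a plain matrix via EBImage
resize_matrix <- function(m, target_r, target_c = target_r, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "nearest") "none" else "bilinear"
  out <- EBImage::resize(EBImage::Image(m), w = target_r, h = target_c, filter = filt)
  matrix(EBImage::imageData(out), target_r, target_c)
}
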