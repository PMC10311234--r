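# Ground-truth construction from multiple human raters: per-pixel majority
# vote, then spatial pooling of votes inside a window to resolve pixels
# where every rater chose a different class.

#' Bundle rater label images into a stack
#'
#' @param labels list of `label_image` rasters from an odd number (>= 3)
#'   of raters, all with identical dimensions
#' @return a `labeler_stack`
#' @export
labeler_stack <- function(labels) {
  if (length(labels) < 3 || length(labels) %% 2 == 0)
    stop("need an odd number of raters, at least 3")
  d <- dim(labels[[1]])
  for (l in labels) {
    if (!all(dim(l) == d)) stop("all rater labels must share dimensions")
    if (!all(l %in% c(0L, 1L, 2L))) stop("invalid classes in rater label")
  }
  structure(list(labels = labels), class = "labeler_stack")
}

# per-class vote count matrices for a stack
vote_counts <- function(stack) {
  lapply(c(LBL_BACKGROUND, LBL_BODY, LBL_NEURITE), function(cl) {
    Reduce(`+`, lapply(stack$labels, function(l) (unclass(l) == cl) * 1))
  })
}

#' Per-pixel majority vote across raters
#'
#' Each rater's label is a vote; a pixel gets the class holding a strict
#' majority.  Pixels without a majority (with three raters: all three
#' disagree) are flagged ambiguous for [spatial_tiebreak()].  Also returns
#' the agreement report: fractions of pixels with unanimous, two-of-three,
#' and no agreement, plus the per-pixel agreement map (3/2/0).
#'
#' @param stack a `labeler_stack`
#' @return list with `partial` (label matrix, NA where ambiguous),
#'   `ambiguous` (logical matrix) and `report` (an `agreement_report`)
#' @export
majority_vote <- function(stack) {
  n <- length(stack$labels)
  V <- vote_counts(stack)
  vmax <- pmax(V[[1]], V[[2]], V[[3]])
  partial <- matrix(NA_integer_, nrow(vmax), ncol(vmax))
  for (cl in 0:2) partial[V[[cl + 1]] > n / 2] <- cl
  ambiguous <- vmax <= n / 2
  agree_map <- matrix(0L, nrow(vmax), ncol(vmax))
  agree_map[vmax == n] <- 3L
  agree_map[vmax == n - 1L] <- 2L
  report <- structure(list(
    frac_unanimous = mean(vmax == n),
    frac_two_of_three = mean(vmax == n - 1L),
    frac_none = mean(vmax <= n - 2L),
    agreement_map = agree_map), class = "agreement_report")
  list(partial = partial, ambiguous = ambiguous, report = report)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: unanimous %.2f%%, partial %.2f%%, none %.2f%%>\n",
              100 * x$frac_unanimous, 100 * x$frac_two_of_three,
              100 * x$frac_none))
  invisible(x)
}

#' Resolve ambiguous pixels by spatial vote pooling
#'
#' Each ambiguous pixel is placed at the center of a `window` x `window`
#' region (truncated at the image borders); the raters' original votes are
#' pooled over the window and across raters, and the plurality class is
#' assigned.  Exact pooled ties stay ambiguous and are retried up to
#' `max_iter` rounds; anything still unresolved is assigned background.
#' Pixels already resolved by [majority_vote()] are never modified.
#'
#' @param partial label matrix with NA at ambiguous pixels
#' @param ambiguous logical matrix flagging ambiguous pixels
#' @param stack the `labeler_stack` providing the votes
#' @param window odd window side in pixels (default 51)
#' @param max_iter pooling rounds before the background fallback
#' @param pitch_um pixel pitch for the returned label
#' @return a fully labeled `label_image`
#' @export
spatial_tiebreak <- function(partial, ambiguous, stack, window = 51L,
                             max_iter = 10L, pitch_um = 0.69) {
  if (window %% 2 != 1) stop("window must be odd")
  half <- (window - 1L) / 2L
  out <- partial
  if (any(ambiguous)) {
    pooled <- lapply(vote_counts(stack), box_sum, half = half)
    open <- which(ambiguous)
    for (it in seq_len(max_iter)) {
      if (!length(open)) break
      cnt <- cbind(pooled[[1]][open], pooled[[2]][open], pooled[[3]][open])
      best <- max.col(cnt, ties.method = "first")
      tie <- cnt[cbind(seq_along(open), best)] ==
        apply(cnt, 1, function(r) sort(r, decreasing = TRUE)[2])
      out[open[!tie]] <- c(LBL_BACKGROUND, LBL_BODY, LBL_NEURITE)[best[!tie]]
      open <- open[tie]
      # votes are fixed, so unresolved ties cannot resolve in later rounds;
      # the loop mirrors the stated procedure and its termination rule
    }
    out[open] <- LBL_BACKGROUND
  }
  out[is.na(out)] <- LBL_BACKGROUND
  label_image(out, pixel_pitch_um = pitch_um)
}

#' Consensus ground truth from a rater stack
#'
#' Convenience wrapper: [majority_vote()] then [spatial_tiebreak()].
#'
#' @inheritParams spatial_tiebreak
#' @param stack a `labeler_stack`
#' @return list with `label` (consensus `label_image`) and `report`
#'   (an `agreement_report`)
#' @export
consensus_labels <- function(stack, window = 51L, max_iter = 10L,
                             pitch_um = 0.69) {
  mv <- majority_vote(stack)
  lab <- spatial_tiebreak(mv$partial, mv$ambiguous, stack, window, max_iter,
                          pitch_um)
  list(label = lab, report = mv$report)
}

#' Encode an agreement map as RGB
#'
#' Blue where all raters agreed, green where a strict majority (but not
#' all) agreed, black where none did.
#'
#' @param report an `agreement_report`
#' @return H x W x 3 array with values 0--255
#' @export
agreement_rgb <- function(report) {
  m <- report$agreement_map
  rgb <- array(0, dim = c(nrow(m), ncol(m), 3))
  rgb[, , 3][m == 3L] <- 255
  rgb[, , 2][m == 2L] <- 255
  rgb
}
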