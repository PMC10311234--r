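# Compact residual U-Net for 3-class segmentation of phase images.
#
# Four resolution levels (1, 1/2, 1/4, 1/8).  Every convolution uses 16
# filters of 3x3 (the stem maps the single input channel to 16, the head
# maps 16 to the 3 class channels).  The four intermediate stages are
# residual blocks with batch normalization (conv-BN-ReLU-conv-BN +
# identity, ReLU); every other shape-compatible stage (outer
# encoder/decoder stages, post-pool transitions, bottleneck, post-merge
# convolutions) carries a parameter-free identity summing connection as
# well, which keeps early SGD stable through the 26-convolution-deep
# path.  Encoder-decoder skip connections are additive summing blocks.
# Downsampling is 2x2 max pooling followed by a convolution; upsampling
# is a stride-2 3x3 transpose convolution followed by the skip addition
# and a convolution.  ReLU everywhere except the final SoftMax over
# (background, cell_body, neurite).
#
# With base_filters = 16 this layout has 56,787 parameters: 56,531
# trainable and 256 non-trainable (8 batch-norm layers x 16 channels x 2
# moving statistics).

CONV_NAMES <- c("c0", "c1a", "c1b", "d1", "r2a", "r2b", "d2", "r3a", "r3b",
                "d3", "b1", "b2", "b3", "u3", "m3", "r4a", "r4b", "u2",
                "m2", "r5a", "r5b", "u1", "m1", "e1a", "e1b", "head")
BN_NAMES <- c("bn2a", "bn2b", "bn3a", "bn3b", "bn4a", "bn4b", "bn5a", "bn5b")
UPCONV_NAMES <- c("u3", "u2", "u1")

#' Residual U-Net architecture specification
#'
#' @param base_filters filters per convolution (default 16)
#' @param kernel convolution kernel side (fixed at 3)
#' @param output_classes number of output channels (fixed at 3)
#' @param bn_momentum moving-statistics momentum of the batch-norm layers
#' @param bn_eps batch-norm variance epsilon
#' @return a `unet_spec`
#' @export
unet_spec <- function(base_filters = 16L, kernel = 3L, output_classes = 3L,
                      bn_momentum = 0.9, bn_eps = 1e-3) {
  if (kernel != 3L) stop("only 3x3 kernels are supported")
  if (output_classes != 3L) stop("the segmenter is fixed at 3 classes")
  if (base_filters < 1) stop("base_filters must be positive")
  structure(list(base_filters = as.integer(base_filters), kernel = 3L,
                 output_classes = 3L, pool_factor = 2L,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "unet_spec")
}

#' Build the residual U-Net
#'
#' Initializes all convolution weights with Glorot-uniform draws and all
#' batch-norm layers with unit gain / zero shift.  Inputs must have sides
#' divisible by 8 (three 2x2 pooling stages).
#'
#' @param spec a `unet_spec`
#' @param seed integer seed for the parameter initialization
#' @return a `resunet` model object
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  set.seed(seed)
  f <- spec$base_filters
  params <- list()
  for (nm in CONV_NAMES) {
    cin <- if (nm == "c0") 1L else f
    cout <- if (nm == "head") spec$output_classes else f
    params[[nm]] <- new_conv(cin, cout)
  }
  bns <- list()
  for (nm in BN_NAMES) bns[[nm]] <- new_bn(f)
  structure(list(spec = spec, conv = params, bn = bns,
                 history = NULL, checkpoints = NULL),
            class = "resunet")
}

#' Parameter counts of a model
#'
#' @param model a `resunet`
#' @return named numeric vector: total, trainable, non_trainable
#' @export
count_params <- function(model) {
  conv_n <- sum(vapply(model$conv, function(cv) length(cv$W) + length(cv$b),
                       numeric(1)))
  bn_train <- sum(vapply(model$bn, function(b) length(b$gamma) + length(b$beta),
                         numeric(1)))
  bn_fixed <- sum(vapply(model$bn,
                         function(b) length(b$moving_mean) + length(b$moving_var),
                         numeric(1)))
  c(total = conv_n + bn_train + bn_fixed,
    trainable = conv_n + bn_train, non_trainable = bn_fixed)
}

#' @export
print.resunet <- function(x, ...) {
  p <- count_params(x)
  cat(sprintf("<resunet: %d conv layers, %d batch-norm layers | params %d (%d trainable, %d non-trainable)>\n",
              length(x$conv), length(x$bn), p["total"], p["trainable"],
              p["non_trainable"]))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final train loss %.4f\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# X: (B*H*W) x 1 input matrix in [0,1].  Returns probabilities and, when
# training, the cache of intermediates needed by unet_backward().
unet_forward <- function(model, X, H, W, B, training = FALSE) {
  sp <- model$spec
  g1 <- nn_geometry(H, W, B)
  g2 <- nn_geometry(H / 2, W / 2, B)
  g3 <- nn_geometry(H / 4, W / 4, B)
  g4 <- nn_geometry(H / 8, W / 8, B)
  cv <- model$conv; bn <- model$bn
  K <- list()   # cache
  cfwd <- function(nm, X, geom) {
    pre <- conv_fwd(X, cv[[nm]], geom)
    K[[nm]] <<- list(X = X, pre = pre)
    relu_fwd(pre)
  }
  resblock <- function(nmA, nmB, bnA, bnB, Xin, geom) {
    pa <- conv_fwd(Xin, cv[[nmA]], geom)
    ba <- bn_fwd(pa, bn[[bnA]], training, sp$bn_eps)
    ra <- relu_fwd(ba$Y)
    pb <- conv_fwd(ra, cv[[nmB]], geom)
    bb <- bn_fwd(pb, bn[[bnB]], training, sp$bn_eps)
    pre <- bb$Y + Xin
    K[[nmA]] <<- list(X = Xin, bn = ba, ra = ra, pb_in = ra)
    K[[nmB]] <<- list(X = ra, bn = bb, sum_pre = pre)
    relu_fwd(pre)
  }
  # parameter-free identity summing at every shape-compatible stage:
  # two-conv residual stage without normalization
  res2 <- function(nmA, nmB, Xin, geom) {
    ha <- cfwd(nmA, Xin, geom)
    pre <- conv_fwd(ha, cv[[nmB]], geom) + Xin
    K[[nmB]] <<- list(X = ha, pre = pre, residual = TRUE)
    relu_fwd(pre)
  }
  # single-conv residual stage
  res1 <- function(nm, Xin, geom) {
    pre <- conv_fwd(Xin, cv[[nm]], geom) + Xin
    K[[nm]] <<- list(X = Xin, pre = pre, residual = TRUE)
    relu_fwd(pre)
  }
  x0 <- cfwd("c0", X, g1)
  s1 <- res2("c1a", "c1b", x0, g1)
  mp1 <- maxpool_fwd(s1, g1); K$mp1 <- mp1
  t1 <- res1("d1", mp1$Y, g2)
  s2 <- resblock("r2a", "r2b", "bn2a", "bn2b", t1, g2)
  mp2 <- maxpool_fwd(s2, g2); K$mp2 <- mp2
  t2 <- res1("d2", mp2$Y, g3)
  s3 <- resblock("r3a", "r3b", "bn3a", "bn3b", t2, g3)
  mp3 <- maxpool_fwd(s3, g3); K$mp3 <- mp3
  t3 <- res1("d3", mp3$Y, g4)
  bo <- res1("b3", res2("b1", "b2", t3, g4), g4)
  up3 <- upconv_fwd(bo, cv$u3, g4, g3); K$u3 <- list(Z = up3$Z, pre = up3$Y)
  a3 <- relu_fwd(up3$Y) + s3                    # skip summing block
  v3 <- resblock("r4a", "r4b", "bn4a", "bn4b", res1("m3", a3, g3), g3)
  up2 <- upconv_fwd(v3, cv$u2, g3, g2); K$u2 <- list(Z = up2$Z, pre = up2$Y)
  a2 <- relu_fwd(up2$Y) + s2
  v2 <- resblock("r5a", "r5b", "bn5a", "bn5b", res1("m2", a2, g2), g2)
  up1 <- upconv_fwd(v2, cv$u1, g2, g1); K$u1 <- list(Z = up1$Z, pre = up1$Y)
  a1 <- relu_fwd(up1$Y) + s1
  e <- res2("e1a", "e1b", res1("m1", a1, g1), g1)
  pre_head <- conv_fwd(e, cv$head, g1)
  K$head <- list(X = e, pre = pre_head)
  probs <- softmax_rows(pre_head)
  if (training) list(probs = probs, cache = K,
                     geoms = list(g1 = g1, g2 = g2, g3 = g3, g4 = g4))
  else probs
}

# dProbs: gradient of the loss w.r.t. the SoftMax probabilities.
# Returns gradients for every conv and BN parameter.
unet_backward <- function(model, fwd, dProbs) {
  sp <- model$spec
  cv <- model$conv; bn <- model$bn
  K <- fwd$cache
  g1 <- fwd$geoms$g1; g2 <- fwd$geoms$g2; g3 <- fwd$geoms$g3; g4 <- fwd$geoms$g4
  gconv <- list(); gbn <- list(); bncache <- list()
  # softmax jacobian
  P <- fwd$probs
  s <- rowSums(dProbs * P)
  dz <- P * (dProbs - s)
  cbwd <- function(nm, dY, geom, through_relu = TRUE) {
    if (through_relu) dY <- relu_bwd(dY, K[[nm]]$pre)
    gr <- conv_bwd(dY, K[[nm]]$X, cv[[nm]], geom)
    gconv[[nm]] <<- list(dW = gr$dW, db = gr$db)
    gr$dX
  }
  res_bwd <- function(nmA, nmB, bnA, bnB, dOut, geom) {
    dpre <- relu_bwd(dOut, K[[nmB]]$sum_pre)
    gB <- bn_bwd(dpre, K[[nmB]]$bn, bn[[bnB]])
    gbn[[bnB]] <<- list(dgamma = gB$dgamma, dbeta = gB$dbeta)
    bncache[[bnB]] <<- K[[nmB]]$bn
    grB <- conv_bwd(gB$dX, K[[nmB]]$X, cv[[nmB]], geom)
    gconv[[nmB]] <<- list(dW = grB$dW, db = grB$db)
    dra <- relu_bwd(grB$dX, K[[nmA]]$bn$Y)
    gA <- bn_bwd(dra, K[[nmA]]$bn, bn[[bnA]])
    gbn[[bnA]] <<- list(dgamma = gA$dgamma, dbeta = gA$dbeta)
    bncache[[bnA]] <<- K[[nmA]]$bn
    grA <- conv_bwd(gA$dX, K[[nmA]]$X, cv[[nmA]], geom)
    gconv[[nmA]] <<- list(dW = grA$dW, db = grA$db)
    grA$dX + dpre          # identity branch of the residual sum
  }
  # parameter-free residual stages: the relu'd sum feeds back both branches
  res2_bwd <- function(nmA, nmB, dOut, geom) {
    dpre <- relu_bwd(dOut, K[[nmB]]$pre)
    grB <- conv_bwd(dpre, K[[nmB]]$X, cv[[nmB]], geom)
    gconv[[nmB]] <<- list(dW = grB$dW, db = grB$db)
    dha <- relu_bwd(grB$dX, K[[nmA]]$pre)
    grA <- conv_bwd(dha, K[[nmA]]$X, cv[[nmA]], geom)
    gconv[[nmA]] <<- list(dW = grA$dW, db = grA$db)
    grA$dX + dpre
  }
  res1_bwd <- function(nm, dOut, geom) {
    dpre <- relu_bwd(dOut, K[[nm]]$pre)
    gr <- conv_bwd(dpre, K[[nm]]$X, cv[[nm]], geom)
    gconv[[nm]] <<- list(dW = gr$dW, db = gr$db)
    gr$dX + dpre
  }
  gr_head <- conv_bwd(dz, K$head$X, cv$head, g1)
  gconv$head <- list(dW = gr_head$dW, db = gr_head$db)
  d <- res2_bwd("e1a", "e1b", gr_head$dX, g1)
  d <- res1_bwd("m1", d, g1)
  # a1 = relu(up1) + s1
  d_s1 <- d
  du <- relu_bwd(d, K$u1$pre)
  gu1 <- upconv_bwd(du, K$u1$Z, cv$u1, g2, g1)
  gconv$u1 <- list(dW = gu1$dW, db = gu1$db)
  d <- res_bwd("r5a", "r5b", "bn5a", "bn5b", gu1$dX, g2)
  d <- res1_bwd("m2", d, g2)
  d_s2 <- d
  du <- relu_bwd(d, K$u2$pre)
  gu2 <- upconv_bwd(du, K$u2$Z, cv$u2, g3, g2)
  gconv$u2 <- list(dW = gu2$dW, db = gu2$db)
  d <- res_bwd("r4a", "r4b", "bn4a", "bn4b", gu2$dX, g3)
  d <- res1_bwd("m3", d, g3)
  d_s3 <- d
  du <- relu_bwd(d, K$u3$pre)
  gu3 <- upconv_bwd(du, K$u3$Z, cv$u3, g4, g3)
  gconv$u3 <- list(dW = gu3$dW, db = gu3$db)
  d <- res1_bwd("b3", gu3$dX, g4)
  d <- res2_bwd("b1", "b2", d, g4)
  d <- res1_bwd("d3", d, g4)
  d <- maxpool_bwd(d, K$mp3$arg, g3)
  d <- res_bwd("r3a", "r3b", "bn3a", "bn3b", d + d_s3, g3)
  d <- res1_bwd("d2", d, g3)
  d <- maxpool_bwd(d, K$mp2$arg, g2)
  d <- res_bwd("r2a", "r2b", "bn2a", "bn2b", d + d_s2, g2)
  d <- res1_bwd("d1", d, g2)
  d <- maxpool_bwd(d, K$mp1$arg, g1)
  d <- res2_bwd("c1a", "c1b", d + d_s1, g1)
  d <- cbwd("c0", d, g1)
  list(conv = gconv, bn = gbn, bn_cache = bncache)
}

# ---- Dice ------------------------------------------------------------------

#' Dice coefficient between flattened prediction and truth
#'
#' `D = 2 * sum(t * p) / (sum(t^2) + sum(p^2))`, with a small epsilon in
#' the denominator guarding the empty-mask case.  Inputs are any equal-
#' length numeric vectors in \[0, 1\] (binary masks or flattened
#' multi-channel stacks).
#'
#' @param y_true,y_pred numeric vectors (or matrices, flattened internally)
#' @param eps denominator guard, default 1e-7
#' @return Dice score in \[0, 1\]
#' @export
dice_coefficient <- function(y_true, y_pred, eps = 1e-7) {
  t <- as.numeric(y_true); p <- as.numeric(y_pred)
  if (length(t) != length(p)) stop("inputs must have equal length")
  2 * sum(t * p) / (sum(t * t) + sum(p * p) + eps)
}

#' Dice loss
#'
#' `1 - D`; zero for a perfect prediction, one for disjoint masks.
#' @inheritParams dice_coefficient
#' @return loss value >= 0
#' @export
dice_loss <- function(y_true, y_pred, eps = 1e-7) {
  1 - dice_coefficient(y_true, y_pred, eps)
}

# per-image Dice loss over a batch plus its gradient w.r.t. probs.
# Tb, Pb: (B*H*W) x 3; loss averaged over the B images.
batch_dice_loss <- function(Tb, Pb, B, eps = 1e-7) {
  n <- nrow(Tb) / B
  loss <- 0
  dP <- matrix(0, nrow(Pb), ncol(Pb))
  for (b in seq_len(B)) {
    rows <- ((b - 1) * n + 1):(b * n)
    t <- Tb[rows, , drop = FALSE]; p <- Pb[rows, , drop = FALSE]
    S1 <- sum(t * p); S2 <- sum(t * t) + sum(p * p) + eps
    loss <- loss + (1 - 2 * S1 / S2)
    dP[rows, ] <- (2 / B) * (2 * S1 * p - S2 * t) / S2^2
  }
  list(loss = loss / B, dP = dP)
}

# ---- training / inference --------------------------------------------------

as_input_matrix <- function(image) {
  m <- unclass(image)
  units <- attr(image, "units") %||% if (max(m) > 1) "uint8" else "normalized"
  if (units == "uint8") m <- m / 255
  else if (units == "radians") { m <- pmax(m, 0); mx <- max(m); if (mx > 0) m <- m / mx }
  matrix(as.numeric(m), ncol = 1)
}

sgd_step <- function(model, grads, lr) {
  for (nm in names(grads$conv)) {
    model$conv[[nm]]$W <- model$conv[[nm]]$W - lr * grads$conv[[nm]]$dW
    model$conv[[nm]]$b <- model$conv[[nm]]$b - lr * grads$conv[[nm]]$db
  }
  for (nm in names(grads$bn)) {
    model$bn[[nm]]$gamma <- model$bn[[nm]]$gamma - lr * grads$bn[[nm]]$dgamma
    model$bn[[nm]]$beta <- model$bn[[nm]]$beta - lr * grads$bn[[nm]]$dbeta
    model$bn[[nm]] <- bn_update_moving(model$bn[[nm]], grads$bn_cache[[nm]],
                                       model$spec$bn_momentum)
  }
  model
}

#' Train the residual U-Net with Dice loss and SGD
#'
#' Plain stochastic gradient descent (no momentum, no schedule) on the
#' three-channel Dice loss.  A fraction of the pairs is held out and its
#' loss monitored each epoch; a parameter snapshot is kept per epoch.
#'
#' @param model a `resunet` from [build_unet()]
#' @param images list of square `phase_image`s (sides divisible by 8)
#' @param labels list of matching `label_image`s
#' @param epochs number of epochs (the reference protocol uses 200)
#' @param batch_size images per SGD step (default 5)
#' @param lr learning rate (default 0.01)
#' @param holdout_fraction fraction reserved to monitor overfitting
#' @param seed seed controlling the holdout split and shuffling
#' @param keep_checkpoints keep a per-epoch parameter snapshot (default TRUE)
#' @param verbose print a line per epoch
#' @return the trained `resunet`; `$history` is a data frame with one row
#'   per epoch (epoch, train_loss, holdout_loss) and `$checkpoints` the
#'   per-epoch snapshots
#' @export
train_unet <- function(model, images, labels, epochs = 200L, batch_size = 5L,
                       lr = 0.01, holdout_fraction = 0.1, seed = 1L,
                       keep_checkpoints = TRUE, verbose = FALSE) {
  if (!length(images)) stop("empty dataset")
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (holdout_fraction < 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be in [0, 1)")
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H %% 8 != 0 || W %% 8 != 0) stop("image sides must be divisible by 8")
  set.seed(seed)
  n <- length(images)
  n_hold <- floor(n * holdout_fraction)
  hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
  train_idx <- setdiff(seq_len(n), hold)
  Xs <- lapply(images, as_input_matrix)
  Ts <- lapply(labels, label_onehot)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        holdout_loss = numeric())
  checkpoints <- list()
  eval_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    tot <- 0
    for (i in idx) {
      p <- unet_forward(model, Xs[[i]], H, W, 1L, training = FALSE)
      tot <- tot + batch_dice_loss(Ts[[i]], p, 1L)$loss
    }
    tot / length(idx)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; n_seen <- 0
    for (bt in batches) {
      B <- length(bt)
      X <- do.call(rbind, Xs[bt])
      Tb <- do.call(rbind, Ts[bt])
      fwd <- unet_forward(model, X, H, W, B, training = TRUE)
      dl <- batch_dice_loss(Tb, fwd$probs, B)
      grads <- unet_backward(model, fwd, dl$dP)
      model <- sgd_step(model, grads, lr)
      ep_loss <- ep_loss + dl$loss * B
      n_seen <- n_seen + B
    }
    hl <- eval_loss(hold)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / n_seen,
                                         holdout_loss = hl))
    if (keep_checkpoints)
      checkpoints[[ep]] <- list(conv = model$conv, bn = model$bn)
    if (verbose)
      cat(sprintf("epoch %3d  train %.4f  holdout %s\n", ep,
                  ep_loss / n_seen, ifelse(is.na(hl), "-", sprintf("%.4f", hl))))
  }
  model$history <- history
  model$checkpoints <- if (keep_checkpoints) checkpoints else NULL
  model
}

#' Per-pixel class probabilities for one image
#'
#' @param model a trained `resunet`
#' @param image square `phase_image` (uint8 images are divided by 255)
#' @return H x W x 3 array of SoftMax scores, channels
#'   (background, cell_body, neurite); rows sum to 1
#' @export
predict_unet <- function(model, image) {
  H <- nrow(image); W <- ncol(image)
  if (H %% 8 != 0 || W %% 8 != 0) stop("image sides must be divisible by 8")
  p <- unet_forward(model, as_input_matrix(image), H, W, 1L, training = FALSE)
  array(p, dim = c(H, W, 3))
}

#' Thresholded segmentation mask for one image
#'
#' Each SoftMax channel is thresholded at `threshold` (default 0.5); a
#' pixel takes the class whose channel exceeds it, and background when no
#' channel does.  With three channels summing to 1, at most one channel
#' can exceed 0.5, so the rule is unambiguous.
#'
#' @inheritParams predict_unet
#' @param threshold per-channel probability threshold
#' @return a `label_image`
#' @export
predict_masks <- function(model, image, threshold = 0.5) {
  pr <- predict_unet(model, image)
  cl <- matrix(LBL_BACKGROUND, nrow(image), ncol(image))
  cl[pr[, , 2] > threshold] <- LBL_BODY
  cl[pr[, , 3] > threshold] <- LBL_NEURITE
  label_image(cl, pixel_pitch_um = attr(image, "pixel_pitch_um") %||% 0.69)
}

#' One-line training summary
#' @param model a trained `resunet`
#' @return data frame with epochs run, final and best losses, parameter total
#' @export
glance_unet <- function(model) {
  p <- count_params(model)
  if (is.null(model$history))
    return(data.frame(epochs = 0L, final_train_loss = NA_real_,
                      best_holdout_loss = NA_real_, n_params = p[["total"]]))
  data.frame(epochs = nrow(model$history),
             final_train_loss = utils::tail(model$history$train_loss, 1),
             best_holdout_loss = suppressWarnings(min(model$history$holdout_loss,
                                                      na.rm = TRUE)),
             n_params = p[["total"]])
}
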