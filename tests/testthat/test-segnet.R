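test_that("the default architecture reproduces the reference parameter counts", {
  m <- build_unet(unet_spec(), seed = 1)
  p <- count_params(m)
  expect_identical(unname(p["total"]), 56787)
  expect_identical(unname(p["trainable"]), 56531)
  expect_identical(unname(p["non_trainable"]), 256)
  # the non-trainable total is the moving statistics of 8 norm layers
  # over 16 channels: 8 * 2 * 16
  expect_identical(unname(p["non_trainable"]) / (2 * 16), 8)
})

test_that("forward pass returns a per-pixel probability simplex", {
  m <- build_unet(seed = 2)
  img <- phase_image(matrix(runif(32 * 32), 32, 32), units = "normalized")
  pr <- predict_unet(m, img)
  expect_identical(dim(pr), c(32L, 32L, 3L))
  sums <- pr[, , 1] + pr[, , 2] + pr[, , 3]
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(predict_unet(m, phase_image(matrix(0.5, 30, 30),
                                           units = "normalized")),
               "divisible")
})

test_that("Dice coefficient and loss match hand-computed cases", {
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1,
               tolerance = 1e-6)
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # 2*1 / (2 + 2) = 0.5
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5,
               tolerance = 1e-6)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0, tolerance = 1e-6)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5, tolerance = 1e-6)
  # epsilon guard: empty masks give a finite (zero) score
  expect_equal(dice_coefficient(numeric(4), numeric(4)), 0)
  expect_error(dice_coefficient(1:3, 1:4), "equal length")
})

test_that("Dice is symmetric and bounded on random inputs", {
  set.seed(8)
  for (i in 1:20) {
    t <- runif(50); p <- runif(50)
    d <- dice_coefficient(t, p)
    expect_equal(d, dice_coefficient(p, t))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(5)
  H <- W <- 16; B <- 1
  m <- build_unet(seed = 5)
  X <- matrix(runif(H * W), ncol = 1)
  lab <- sample(0:2, H * W, TRUE)
  Tb <- cbind(lab == 0, lab == 1, lab == 2) * 1
  fwd <- neuroqpi:::unet_forward(m, X, H, W, B, training = TRUE)
  dl <- neuroqpi:::batch_dice_loss(Tb, fwd$probs, B)
  gr <- neuroqpi:::unet_backward(m, fwd, dl$dP)
  eps <- 1e-6
  for (nm in c("c0", "r2b", "u3", "head")) {
    idx <- 7L
    m2 <- m
    m2$conv[[nm]]$W[idx] <- m2$conv[[nm]]$W[idx] + eps
    f2 <- neuroqpi:::unet_forward(m2, X, H, W, B, training = TRUE)
    num <- (neuroqpi:::batch_dice_loss(Tb, f2$probs, B)$loss - dl$loss) / eps
    expect_equal(gr$conv[[nm]]$dW[idx], num, tolerance = 1e-3)
  }
})

test_that("training descends, logs history, and is reproducible", {
  set.seed(77)
  cfg <- tiny_growth_config(grid_px = 32L, field_size_um = 22.08,
                            n_neurons_min = 1L, n_neurons_max = 2L)
  pairs <- simulate_training_pairs(cfg, 3, 1:2, seed = 42)
  imgs <- lapply(pairs, `[[`, "image"); labs <- lapply(pairs, `[[`, "label")
  m <- build_unet(seed = 3)
  m <- train_unet(m, imgs, labs, epochs = 3, batch_size = 2,
                  holdout_fraction = 0, seed = 10, keep_checkpoints = TRUE)
  expect_identical(nrow(m$history), 3L)
  expect_lt(m$history$train_loss[3], m$history$train_loss[1])
  expect_length(m$checkpoints, 3)

  m2 <- build_unet(seed = 3)
  m2 <- train_unet(m2, imgs, labs, epochs = 3, batch_size = 2,
                   holdout_fraction = 0, seed = 10, keep_checkpoints = FALSE)
  expect_identical(m$history, m2$history)
  expect_error(train_unet(build_unet(), list(), list()), "empty")
})

test_that("the model can overfit a single pair to near-zero Dice loss", {
  cfg <- tiny_growth_config(grid_px = 32L, field_size_um = 22.08,
                            n_neurons_min = 2L, n_neurons_max = 2L)
  pair <- simulate_training_pairs(cfg, 1, 2, seed = 6)[[1]]
  m <- build_unet(seed = 8)
  reached <- FALSE
  for (chunk in 1:20) {   # up to 200 gradient steps, checked every 10
    m <- train_unet(m, list(pair$image), list(pair$label), epochs = 10,
                    batch_size = 1, holdout_fraction = 0, seed = chunk,
                    keep_checkpoints = FALSE)
    if (utils::tail(m$history$train_loss, 1) < 0.1) { reached <- TRUE; break }
  }
  expect_true(reached)
})

test_that("mask prediction thresholds each SoftMax channel at 0.5", {
  m <- build_unet(seed = 4)
  img <- phase_image(matrix(runif(32 * 32), 32, 32), units = "normalized")
  pr <- predict_unet(m, img)
  pm <- predict_masks(m, img)
  manual <- matrix(0L, 32, 32)
  manual[pr[, , 2] > 0.5] <- 1L
  manual[pr[, , 3] > 0.5] <- 2L
  expect_identical(matrix(pm, 32, 32), manual)
  # at most one channel of a 3-way SoftMax can exceed 0.5
  expect_true(all((pr[, , 1] > 0.5) + (pr[, , 2] > 0.5) + (pr[, , 3] > 0.5) <= 1))
  # thresholding one-hot probabilities is idempotent
  oh <- neuroqpi:::label_onehot(unclass(pm))
  rethresh <- matrix(0L, 32, 32)
  rethresh[matrix(oh[, 2], 32, 32) > 0.5] <- 1L
  rethresh[matrix(oh[, 3], 32, 32) > 0.5] <- 2L
  expect_identical(rethresh, matrix(pm, 32, 32))
})
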