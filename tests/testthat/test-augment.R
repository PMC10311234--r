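test_that("sampled parameters respect the clamped bounds and frequencies", {
  set.seed(314)
  draws <- replicate(10000, sample_augment_params(), simplify = FALSE)
  scales <- vapply(draws, `[[`, numeric(1), "scale")
  gammas <- vapply(draws, `[[`, numeric(1), "gamma")
  expect_true(all(scales >= 0.5 & scales <= 1.5))
  expect_true(all(gammas >= 0.7 & gammas <= 1.7))
  # clamping piles mass at the bounds but values inside still dominate
  expect_gt(mean(scales > 0.5 & scales < 1.5), 0.9)

  flips <- vapply(draws, `[[`, character(1), "flip")
  rots <- vapply(draws, `[[`, integer(1), "rotation")
  se <- 3 * sqrt(0.25 * 0.75 / length(draws))
  for (f in c("none", "lr", "ud", "lrud"))
    expect_lt(abs(mean(flips == f) - 0.25), se)
  for (r in c(0L, 90L, 180L, 270L))
    expect_lt(abs(mean(rots == r) - 0.25), se)

  set.seed(11); p1 <- sample_augment_params()
  set.seed(11); p2 <- sample_augment_params()
  expect_identical(p1, p2)
})

test_that("identity parameters leave the pair unchanged", {
  img <- toy_image(); lab <- toy_label()
  p <- structure(list(scale = 1, flip = "none", rotation = 0L, gamma = 1,
                      crop_u = c(0.5, 0.5)), class = "augment_params")
  out <- apply_augment(img, lab, p)
  expect_equal(unclass(out$image), unclass(img))
  expect_identical(unclass(out$label), unclass(lab))
})

test_that("gamma touches only the image and fixes the extremes", {
  img <- toy_image(); lab <- toy_label()
  base <- structure(list(scale = 0.8, flip = "lr", rotation = 90L, gamma = 1,
                         crop_u = c(0.3, 0.6)), class = "augment_params")
  warped <- base; warped$gamma <- 1.5
  a <- apply_augment(img, lab, base)
  b <- apply_augment(img, lab, warped)
  expect_identical(unclass(a$label), unclass(b$label))
  expect_false(identical(unclass(a$image), unclass(b$image)))
  # fixed points of the power law on the normalized scale
  x <- c(0, 1)
  expect_equal(x^1.5, x)
  full <- phase_image(matrix(rep(c(0, 255), length.out = 64 * 64), 64, 64),
                      units = "uint8")
  idp <- base; idp$scale <- 1; idp$flip <- "none"; idp$rotation <- 0L
  idp$gamma <- 1.5
  g <- apply_augment(full, label_image(matrix(0L, 64, 64)), idp)
  expect_setequal(unique(as.vector(unclass(g$image))), c(0, 255))
})

test_that("flips and right-angle rotations preserve class counts exactly", {
  img <- toy_image(); lab <- toy_label()
  for (fl in c("lr", "ud", "lrud")) for (ro in c(0L, 90L, 180L, 270L)) {
    p <- structure(list(scale = 1, flip = fl, rotation = ro, gamma = 1,
                        crop_u = c(0, 0)), class = "augment_params")
    out <- apply_augment(img, lab, p)
    expect_identical(table(unclass(out$label)), table(unclass(lab)))
    # alignment: transforming the label-derived mask equals the label of
    # the transformed pair
    expect_identical(unclass(out$label) == 2L,
                     {m <- unclass(lab) == 2L
                      m <- switch(fl, lr = m[, ncol(m):1], ud = m[nrow(m):1, ],
                                  lrud = m[nrow(m):1, ncol(m):1])
                      for (k in seq_len(ro / 90)) m <- t(m)[nrow(m):1, ]
                      m})
  }
})

test_that("rescaling keeps dimensions and approximate geometry", {
  img <- toy_image(); lab <- toy_label()
  up <- structure(list(scale = 1.4, flip = "none", rotation = 0L, gamma = 1,
                       crop_u = c(0, 0)), class = "augment_params")
  dn <- structure(list(scale = 0.6, flip = "none", rotation = 0L, gamma = 1,
                       crop_u = c(0.2, 0.2)), class = "augment_params")
  for (p in list(up, dn)) {
    out <- apply_augment(img, lab, p)
    expect_identical(dim(out$image), dim(img))
    expect_identical(dim(out$label), dim(lab))
    expect_true(all(unclass(out$label) %in% 0:2))
  }
  # scale > 1 shrinks content: fewer body pixels than the original
  expect_lt(sum(unclass(apply_augment(img, lab, up)$label) == 1L),
            sum(unclass(lab) == 1L))
  expect_error(apply_augment(img, toy_label(32), up), "mismatch")
})

test_that("dataset construction samples sources uniformly and subsamples", {
  src <- list(
    list(image = toy_image(), label = toy_label(), source_id = "real1"),
    list(image = toy_image(), label = toy_label(), source_id = "sim1"))
  ds <- build_augmented_dataset(src, n_generate = 50, n_subsample = 5, seed = 3)
  expect_length(ds$pairs, 5)
  expect_identical(nrow(ds$manifest), 5L)
  expect_true(all(dim(ds$pairs[[1]]$image) == dim(toy_image())))

  # mixed pool 1 real + 9 simulated: expected simulated fraction 0.9
  pool <- c(list(list(image = toy_image(), label = toy_label(), source_id = "real")),
            lapply(1:9, function(i) list(image = toy_image(), label = toy_label(),
                                         source_id = paste0("sim", i))))
  ds2 <- build_augmented_dataset(pool, n_generate = 2000, n_subsample = 10, seed = 4)
  gen <- attr(ds2$manifest, "generated_source_index")
  frac_sim <- mean(gen > 1)
  expect_lt(abs(frac_sim - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))

  expect_error(build_augmented_dataset(list(), 10, 5), "non-empty")
  expect_error(build_augmented_dataset(src, 10, 50))
})
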