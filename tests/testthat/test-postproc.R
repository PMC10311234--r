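# independent brute-force mass oracle: explicit per-pixel loop
dry_mass_oracle <- function(phase, mask, lambda = 0.6328, alpha = 0.2,
                            pitch = 0.345) {
  acc <- 0
  for (i in seq_len(nrow(phase))) for (j in seq_len(ncol(phase)))
    if (mask[i, j]) acc <- acc + lambda / (2 * pi * alpha) *
      phase[i, j] * pitch^2
  acc
}

test_that("size filtering removes exactly the sub-threshold regions", {
  # 100 px at 0.69 um -> 47.61 um^2 < 714 -> removed
  lab <- matrix(0L, 64, 64)
  lab[1:10, 1:10] <- 1L
  l <- label_image(lab, pixel_pitch_um = 0.69)
  out <- size_filter(l, region_filter_config(min_area_um2 = 714))
  expect_true(all(out == 0L))
  # the same region survives a 40 um^2 threshold
  out2 <- size_filter(l, region_filter_config(min_area_um2 = 40))
  expect_equal(matrix(out2, 64, 64), lab)
  # threshold 0: unchanged; empty label: unchanged
  expect_equal(matrix(size_filter(l, region_filter_config(min_area_um2 = 0)), 64, 64), lab)
  empty <- label_image(matrix(0L, 16, 16))
  expect_identical(unclass(size_filter(empty)), unclass(empty))
  # surviving pixels keep their class
  mixed <- matrix(0L, 64, 64); mixed[1:40, 1:40] <- 1L; mixed[10, 1:45] <- 2L
  keep <- size_filter(label_image(mixed, 0.69), region_filter_config(714))
  expect_identical(sort(unique(as.vector(keep))), c(0L, 1L, 2L))
})

test_that("foreground shrinks monotonically in the area threshold", {
  set.seed(30)
  lab <- matrix(0L, 96, 96)
  for (k in 1:8) {
    r <- sample(5:80, 1); c <- sample(5:80, 1); s <- sample(2:12, 1)
    lab[r:min(96, r + s), c:min(96, c + s)] <- 1L
  }
  l <- label_image(lab, 0.69)
  fg <- vapply(c(10, 50, 100, 300, 714, 1200), function(thr)
    sum(size_filter(l, region_filter_config(thr)) > 0L), numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("the threshold sweep picks the Dice-optimal area cut", {
  cfg <- region_filter_config(pixel_pitch_um = 0.69)
  expect_identical(cfg$sweep_range, seq(119, 1071, by = 119))
  expect_length(cfg$sweep_range, 9L)

  # perfect predictions: every threshold ties at Dice 1 -> smallest returned
  truth <- toy_label()
  big <- matrix(0L, 64, 64); big[5:60, 5:50] <- 1L   # 2556 px ~ 1217 um^2
  tr <- label_image(big, 0.69)
  thr <- select_area_threshold(list(tr), list(tr), cfg)
  expect_identical(as.numeric(thr), 119)

  # planted noise < 500 um^2 on top of true regions > 1200 um^2:
  # the best threshold must clear the spurious set without touching truth
  noisy <- big
  noisy[1:2, 55:64] <- 1L          # 20 px ~ 9.5 um^2 spurious
  noisy[62:64, 58:64] <- 2L        # 21 px ~ 10 um^2 spurious
  pred <- label_image(noisy, 0.69)
  thr2 <- select_area_threshold(list(pred), list(tr), cfg)
  sweep <- attr(thr2, "sweep")
  expect_identical(nrow(sweep), 9L)
  expect_gte(sweep$dice[sweep$threshold == as.numeric(thr2)][1],
             max(sweep$dice) - 1e-12)
  expect_true(as.numeric(thr2) >= 119 && as.numeric(thr2) <= 1071)
  expect_error(select_area_threshold(list(), list(), cfg))
})

test_that("dry mass matches the closed form, the oracle, and is linear", {
  # uniform phase 1 rad over 10,000 px at 0.345 um
  phase <- phase_image(matrix(1, 100, 100), pixel_pitch_um = 0.345,
                       units = "radians")
  mask <- matrix(TRUE, 100, 100)
  m <- dry_mass(phase, mask)
  closed <- 0.6328 / (2 * pi * 0.2) * 10000 * 0.345^2
  expect_equal(m, closed, tolerance = 1e-12)
  expect_equal(closed, 599.3, tolerance = 1e-3)   # 599.346... pg

  expect_identical(dry_mass(phase, matrix(FALSE, 100, 100)), 0)
  expect_equal(dry_mass(phase_image(unclass(phase) * 2, 0.345, "radians"), mask),
               2 * m)

  set.seed(9)
  ph <- phase_image(matrix(rexp(400, 2), 20, 20), 0.345, "radians")
  mk <- matrix(runif(400) > 0.5, 20, 20)
  expect_equal(dry_mass(ph, mk), dry_mass_oracle(ph, mk), tolerance = 1e-10)
  # additivity over disjoint masks
  mk2 <- !mk
  expect_equal(dry_mass(ph, mk) + dry_mass(ph, mk2),
               dry_mass(ph, matrix(TRUE, 20, 20)))
  expect_error(dry_mass(ph, mk, wavelength_um = -1))
})

test_that("percent mass differences behave on constructed labels", {
  ph <- phase_image(matrix(1, 64, 64), 0.345, "radians")
  lab <- toy_label()
  same <- percent_diff_mass(lab, lab, ph)
  expect_true(all(same$pct_diff == 0))
  expect_equal(same$mass_pred_pg[same$compartment == "whole"],
               same$mass_pred_pg[same$compartment == "cell_body"] +
                 same$mass_pred_pg[same$compartment == "neurite"])

  # prediction missing half the body pixels of a uniform-phase cell -> 50%
  m <- matrix(0L, 64, 64); m[10:25, 12:31] <- 1L
  half <- m; half[10:25, 12:21] <- 0L    # drop 10 of 20 columns
  res <- percent_diff_mass(label_image(half, 0.69), label_image(m, 0.69), ph)
  expect_equal(res$pct_diff[res$compartment == "cell_body"], 50)
  # empty true neurite -> undefined percent difference
  expect_true(is.na(res$pct_diff[res$compartment == "neurite"]))

  agg <- aggregate_mass_diff(list(res, res, res))
  expect_equal(agg$sem[agg$compartment == "cell_body"], 0)
  expect_identical(agg$n[agg$compartment == "cell_body"], 3L)
  # SEM = sd / sqrt(N) on a spread of values
  r2 <- res; r2$pct_diff[2] <- 20
  agg2 <- aggregate_mass_diff(list(res, r2))
  expect_equal(agg2$sem[agg2$compartment == "cell_body"],
               stats::sd(c(50, 20)) / sqrt(2))
})

test_that("the Dice suite scores all four granularities", {
  lab <- toy_label()
  ident <- evaluate_dice_suite(lab, lab)
  expect_true(all(abs(ident - 1) < 1e-6))

  swapped <- unclass(lab)
  tmp <- swapped == 1L
  swapped[swapped == 2L] <- 1L
  swapped[tmp] <- 2L
  sw <- evaluate_dice_suite(label_image(swapped), lab)
  expect_equal(unname(sw["cell_vs_not"]), 1, tolerance = 1e-6)
  expect_lt(sw["cell_body"], 1)
  expect_lt(sw["neurite"], 1)

  # the 4-pixel hand example embeds as a one-hot 3-channel score of 0.5
  a <- label_image(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  b <- label_image(matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_equal(unname(evaluate_dice_suite(b, a)["three_channel"]), 0.5,
               tolerance = 1e-6)
})

test_that("phase-to-uint8 conversion follows the stated arithmetic", {
  ph <- phase_image(matrix(c(-1, 0, 2, 4), 2, 2), 0.345, "radians")
  out <- qpi_to_uint8(ph)
  expect_identical(sort(as.vector(out)), c(0, 0, 127, 255))
  allneg <- qpi_to_uint8(phase_image(matrix(-runif(16), 4, 4), 0.345, "radians"))
  expect_true(all(allneg == 0))
  # the maximum always maps to 255; idempotent up to quantization
  set.seed(2)
  ph2 <- phase_image(matrix(runif(64, 0, 3), 8, 8), 0.345, "radians")
  u1 <- qpi_to_uint8(ph2)
  expect_identical(max(u1), 255)
  u2 <- qpi_to_uint8(phase_image(unclass(u1), 0.345, "radians"))
  expect_true(all(abs(u1 - u2) <= 1))
})

test_that("cell extents report per-region bounding boxes in micrometers", {
  lab <- matrix(0L, 64, 64)
  lab[11:20, 6:25] <- 1L    # 10 x 20 px body
  ext <- cell_extents(label_image(lab, 0.69))
  expect_identical(nrow(ext), 1L)
  expect_equal(ext$extent_y_um, 10 * 0.69)
  expect_equal(ext$extent_x_um, 20 * 0.69)
  expect_equal(ext$major_um, 13.8)
  expect_equal(ext$minor_um, 6.9)

  expect_identical(nrow(cell_extents(label_image(matrix(0L, 8, 8)))), 0L)
  lab[40:45, 40:45] <- 1L
  expect_identical(nrow(cell_extents(label_image(lab, 0.69))), 2L)
})
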