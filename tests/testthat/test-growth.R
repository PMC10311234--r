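test_that("dish initialization respects the configured neuron count", {
  cfg <- growth_config(n_neurons_min = 1, n_neurons_max = 1, n_steps = 0)
  tl <- init_dish(cfg, seed = 7)
  expect_identical(nrow(tl$soma_centers), 1L)

  counts <- vapply(1:200, function(s) {
    nrow(init_dish(growth_config(n_steps = 0), seed = s)$soma_centers)
  }, integer(1))
  expect_true(all(counts >= 1 & counts <= 10))
  expect_gt(length(unique(counts)), 3)   # actually samples the range
})

test_that("identical (config, seed) gives identical timelines and rasters", {
  cfg <- tiny_growth_config()
  a <- simulate_dish(cfg, seed = 11)
  b <- simulate_dish(cfg, seed = 11)
  expect_identical(a$segments, b$segments)
  expect_identical(a$soma_centers, b$soma_centers)
  expect_identical(rasterize_skeleton(a), rasterize_skeleton(b))
  c <- simulate_dish(cfg, seed = 12)
  expect_false(identical(a$segments, c$segments))
})

test_that("elongation with zero variance produces exact segment lengths", {
  cfg <- tiny_growth_config(elongation_sd_um = 0, branch_base_prob = 0,
                            turn_sd_rad = 0)
  tl <- simulate_dish(cfg, seed = 2)
  segs <- tl$segments
  full <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  # boundary-clipped segments are shorter; all others must be exact
  interior <- segs$x1 > 0 & segs$x1 < cfg$field_size_um &
    segs$y1 > 0 & segs$y1 < cfg$field_size_um
  expect_true(all(abs(full[interior] - cfg$elongation_mean_um) < 1e-9))
})

test_that("branching probability follows the order-damped closed form", {
  # base 0.2, sensitivity 1, order 2 -> per-step branch probability 0.05
  cfg <- growth_config(branch_base_prob = 0.2, branch_order_sensitivity = 1,
                       elongation_mean_um = 0.01, elongation_sd_um = 0,
                       turn_sd_rad = 0, n_steps = 1)
  n_cones <- 10000L
  tl <- init_dish(cfg, seed = 5)
  tl$cones <- data.frame(x = rep(176, n_cones), y = rep(176, n_cones),
                         heading = runif(n_cones, 0, 2 * pi),
                         order = 2L, neuron_id = 1L, active = TRUE)
  set.seed(99)
  tl2 <- step_cones(tl, 1)
  n_branched <- nrow(tl2$cones) - n_cones
  p_expect <- 0.2 * 2^(-1 * 2)
  se <- sqrt(p_expect * (1 - p_expect) / n_cones)
  expect_lt(abs(n_branched / n_cones - p_expect), 3 * se)
})

test_that("infinite order sensitivity suppresses branching beyond order 0", {
  cfg <- tiny_growth_config(branch_base_prob = 1,
                            branch_order_sensitivity = Inf)
  tl <- simulate_dish(cfg, seed = 3)
  # order-0 cones branch on step 1 (prob 1); daughters at order 1 never do,
  # so no segment of order 2 can ever appear
  expect_true(all(tl$segments$order <= 1L))
})

test_that("growth is monotone and snapshots accumulate", {
  cfg <- tiny_growth_config(n_steps = 5)
  tl <- simulate_dish(cfg, seed = 4)
  lens <- vapply(0:5, function(s) total_path_length(tl, s), numeric(1))
  expect_true(all(diff(lens) >= 0))
  counts <- vapply(0:5, function(s) nrow(segments_at_step(tl, s)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0)
  # zero steps: somata only
  tl0 <- simulate_dish(tiny_growth_config(n_steps = 0), seed = 4)
  expect_identical(nrow(tl0$segments), 0L)
})

test_that("step_cones rejects out-of-range steps and bad configs error", {
  cfg <- tiny_growth_config()
  tl <- init_dish(cfg, seed = 1)
  expect_error(step_cones(tl, cfg$n_steps + 1), "step_index")
  expect_error(growth_config(n_neurons_min = 5, n_neurons_max = 2))
  expect_error(growth_config(branch_base_prob = 1.5))
  expect_error(growth_config(elongation_sd_um = -1))
})

test_that("skeleton rasterization draws 1-px-wide in-field lines", {
  cfg <- tiny_growth_config(n_steps = 0)
  tl <- init_dish(cfg, seed = 1)
  empty <- rasterize_skeleton(tl)
  expect_true(all(empty == 0L))

  # one horizontal 10-px segment: between 10 and 12 lit pixels, all 255
  pitch <- pixel_pitch(cfg)
  tl$segments <- data.frame(neuron_id = 1L, order = 0L, birth_step = 1L,
                            x0 = 10 * pitch, y0 = 20 * pitch,
                            x1 = 20 * pitch, y1 = 20 * pitch)
  tl$step <- 1L
  ras <- rasterize_skeleton(tl, 1)
  lit <- sum(ras == 255L)
  expect_gte(lit, 10); expect_lte(lit, 12)
  expect_setequal(unique(as.vector(ras)), c(0L, 255L))
})

test_that("every rasterized neurite tree is 8-connected to its soma pixel", {
  cfg <- tiny_growth_config(n_neurons_min = 1, n_neurons_max = 1, n_steps = 4)
  for (s in 1:3) {
    tl <- simulate_dish(cfg, seed = s)
    ras <- rasterize_skeleton(tl)
    if (!any(ras > 0)) next
    lab <- label_regions(ras > 0, connectivity = 8)
    pitch <- pixel_pitch(cfg)
    sr <- floor(tl$soma_centers[1, 2] / pitch) + 1
    sc <- floor(tl$soma_centers[1, 1] / pitch) + 1
    # all skeleton pixels belong to the single component holding the soma
    expect_identical(max(lab), lab[sr, sc])
    expect_identical(max(lab), 1L)
  }
})

test_that("segment tables round-trip through CSV", {
  cfg <- tiny_growth_config()
  tl <- simulate_dish(cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(tl, path)
  back <- read_segments_csv(path, cfg)
  expect_equal(back$segments$x0, tl$segments$x0)
  expect_equal(back$segments$birth_step, tl$segments$birth_step)
  expect_identical(rasterize_skeleton(back, tl$step), rasterize_skeleton(tl))
})
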