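# End-to-end convenience layer: generate dishes, render image/label pairs,
# and run the scaled-down demonstration study used in the examples and
# the test suite.

#' Desk-scale growth configuration
#'
#' A reduced field for fast end-to-end runs: 128 px over 88.32 um (the
#' same 0.69 um pitch as the full 512-px field), 5 growth steps and 2--4
#' neurons per dish so that the foreground classes are well represented in
#' every rendered frame.  Growth rates are the full-scale defaults.
#'
#' @param ... overrides passed to [growth_config()]
#' @return a `growth_config`
#' @export
demo_growth_config <- function(...) {
  growth_config(field_size_um = 88.32, grid_px = 128L, n_steps = 5L,
                n_neurons_min = 2L, n_neurons_max = 4L, ...)
}

#' Simulate and render a set of image/label pairs
#'
#' Simulates `n_dishes` independent Petri dishes and renders each at the
#' requested time steps, giving `n_dishes * length(steps)` image/label
#' pairs.
#'
#' @param config a `growth_config`
#' @param n_dishes number of dishes
#' @param steps time steps to render (default: every step)
#' @param render_cfg a `render_config`
#' @param seed integer seed; dish d uses substream (seed, "dish<d>")
#' @return list of `list(image =, label =, dish =, step =)`
#' @export
simulate_training_pairs <- function(config, n_dishes,
                                    steps = seq_len(config$n_steps),
                                    render_cfg = render_config(), seed = 1L) {
  out <- list()
  for (d in seq_len(n_dishes)) {
    dseed <- derive_seed(seed, paste0("dish", d))
    tl <- simulate_dish(config, seed = dseed)
    for (s in steps) {
      r <- render_dish(tl, s, render_cfg, seed = dseed)
      out[[length(out) + 1L]] <- list(image = r$image, label = r$label,
                                      dish = d, step = s)
    }
  }
  out
}

#' Scaled-down end-to-end study
#'
#' The full protocol in miniature: simulate training dishes, render
#' image/label pairs, train the residual U-Net with Dice loss, and score
#' thresholded predictions on freshly simulated held-out dishes with the
#' Dice suite.  Defaults follow the package's demonstration conditions
#' (see the methods vignette): 10 training dishes x 5 steps at 128 px,
#' 5 epochs, batch 5, lr 0.01.
#'
#' @param n_train_dishes,n_test_dishes dishes for training / held-out testing
#' @param steps_per_dish rendered steps per dish
#' @param epochs,batch_size,lr training protocol
#' @param seed master seed for simulation, rendering, initialization and
#'   training
#' @param config a `growth_config` (desk-scale by default)
#' @param verbose print per-epoch losses
#' @return list: `model`, `dice` (data frame of per-test-image suites),
#'   `whole_cell_dice` (overall cell-vs-not Dice across the held-out set),
#'   `history`
#' @export
run_demo_study <- function(n_train_dishes = 10L, n_test_dishes = 2L,
                           steps_per_dish = 5L, epochs = 5L, batch_size = 5L,
                           lr = 0.01, seed = 1L,
                           config = demo_growth_config(), verbose = FALSE) {
  steps <- seq_len(steps_per_dish)
  train <- simulate_training_pairs(config, n_train_dishes, steps,
                                   seed = derive_seed(seed, "train"))
  test <- simulate_training_pairs(config, n_test_dishes, steps,
                                  seed = derive_seed(seed, "test"))
  model <- build_unet(unet_spec(), seed = derive_seed(seed, "init"))
  model <- train_unet(model,
                      images = lapply(train, `[[`, "image"),
                      labels = lapply(train, `[[`, "label"),
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      holdout_fraction = 0,
                      seed = derive_seed(seed, "sgd"),
                      keep_checkpoints = FALSE, verbose = verbose)
  suites <- list(); pred_oh <- list(); true_oh <- list()
  pred_bin <- list(); true_bin <- list()
  for (i in seq_along(test)) {
    pm <- predict_masks(model, test[[i]]$image)
    suites[[i]] <- as.data.frame(t(evaluate_dice_suite(pm, test[[i]]$label)))
    pred_bin[[i]] <- as.numeric(unclass(pm) > 0L)
    true_bin[[i]] <- as.numeric(unclass(test[[i]]$label) > 0L)
  }
  whole <- dice_coefficient(unlist(true_bin), unlist(pred_bin))
  list(model = model, dice = do.call(rbind, suites),
       whole_cell_dice = whole, history = model$history)
}
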