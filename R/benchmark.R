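#' Run the scaled-down separation benchmark
#'
#' End-to-end experiment used for reduced-scale validation: generate a
#' phantom dataset, train the semi-Siamese separation network (optionally
#' also the dual U-Net baseline) for a fixed epoch budget over several
#' seeds, and evaluate per-organ Dice and MAE on the held-out test split.
#'
#' The default problem size — a 64 x 64 pixel grid, a roughly 500-element
#' mesh, a 300-scene radius grid, a width-scale-1/4 network and 30 epochs at
#' batch size 8 and learning rate 1e-4 — is the package's standard
#' desk-scale regime (see the methods vignette for the rationale behind
#' these sizes).
#'
#' @param lung_steps,heart_steps Scene grid (default 20 x 15 = 300 scenes).
#' @param n_elements,grid_size Simulation scale (default 512 elements,
#'   64 px).
#' @param width_scale Network width relative to the full-scale 64 base
#'   filters (default 1/4).
#' @param epochs Training epochs per seed (default 30).
#' @param seeds Integer vector of training seeds; metrics are reported per
#'   seed and as the across-seed median.
#' @param split_seed Seed of the train/val/test shuffle.
#' @param weights [loss_weights()] for the semi-Siamese run.
#' @param baseline Also train the dual U-Net baseline at the same budget.
#' @param keep_fit Keep the last seed's fitted model (for fine-tuning
#'   experiments).
#' @param dataset Optional pre-built normalized dataset (skips simulation).
#' @param checkpoint_every Checkpoint period passed to [train_config()].
#' @param progress Emit progress messages.
#' @return List with `per_seed` (tibble of organ metrics per seed and
#'   model), `median` (across-seed medians), the `dataset` (invisibly
#'   reusable), and optionally `fit`.
#' @export
run_separation_benchmark <- function(lung_steps = 20L, heart_steps = 15L,
                                     n_elements = 512L, grid_size = 64L,
                                     width_scale = 1 / 4, epochs = 30L,
                                     seeds = c(1L, 2L, 3L),
                                     split_seed = 42L,
                                     weights = loss_weights(),
                                     baseline = FALSE, keep_fit = FALSE,
                                     dataset = NULL,
                                     checkpoint_every = 10L,
                                     progress = FALSE) {
  say <- function(...) if (progress) message(...)
  if (is.null(dataset)) {
    say("simulating ", lung_steps * heart_steps, " scenes ...")
    ctx <- make_sim_context(n_elements = n_elements, grid_size = grid_size)
    dataset <- build_dataset(enumerate_scenarios(lung_steps, heart_steps),
                             ctx)
    dataset <- normalize_dataset(dataset,
                                 split_dataset(dataset, seed = split_seed))
  }
  spec <- separation_model_spec(dataset$grid_size, 64L,
                                width_scale = width_scale)
  rows <- list()
  fit_keep <- NULL
  for (sd in seeds) {
    say("training semi-Siamese, seed ", sd, " ...")
    cfg <- train_config(epochs = epochs, checkpoint_every = checkpoint_every,
                        seed = sd, weights = weights,
                        validate_every = max(1L, checkpoint_every))
    fit <- train_separation(build_semi_siamese(spec, seed = sd), dataset,
                            config = cfg)
    mr <- evaluate_model(fit, dataset, model_label = "semi_siamese")
    mr$seed <- sd
    rows[[length(rows) + 1]] <- mr
    if (baseline) {
      say("training dual U-Net baseline, seed ", sd, " ...")
      dfit <- train_separation(build_dual_unet(spec, seed = sd), dataset,
                               config = cfg)
      mb <- evaluate_model(dfit, dataset, model_label = "dual_unet")
      mb$seed <- sd
      rows[[length(rows) + 1]] <- mb
    }
    if (keep_fit) fit_keep <- fit
  }
  per_seed <- do.call(rbind, rows)
  agg <- stats::aggregate(
    per_seed[, c("dice_percent", "mae_percent")],
    by = list(model = per_seed$model, organ = per_seed$organ),
    FUN = stats::median)
  med <- tibble::as_tibble(agg)
  list(per_seed = tibble::as_tibble(per_seed), median = med,
       dataset = dataset, fit = fit_keep)
}
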