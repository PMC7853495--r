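# Multi-task loss, optimization loop, checkpointing, fine-tuning.

test_that("weighted multi-task loss follows the stated combination rule", {
  set.seed(2)
  p <- matrix(runif(16, 0.05, 0.95), 4)
  t <- matrix(runif(16), 4)
  bce_ref <- function(p, t) mean(-(t * log(p) + (1 - t) * log(1 - p)))
  l <- bce_ref(p, t)
  # equal per-task losses with unit weights sum to twice the task loss
  expect_equal(multitask_loss(p, t, p, t, loss_weights(1, 1)), 2 * l)
  # zero lung weight leaves only the heart term
  p2 <- matrix(runif(16, 0.05, 0.95), 4); t2 <- matrix(runif(16), 4)
  expect_equal(multitask_loss(p, t, p2, t2, loss_weights(0, 1)),
               bce_ref(p2, t2))
  # hand-computed 4-pixel oracle at weights (1, 1.8)
  pl <- matrix(c(0.8, 0.2, 0.6, 0.4), 2)
  tl <- matrix(c(1, 0, 1, 0), 2)
  ph <- matrix(c(0.7, 0.3, 0.9, 0.1), 2)
  th <- matrix(c(1, 1, 0, 0), 2)
  hand_l <- -(log(0.8) + log(1 - 0.2) + log(0.6) + log(1 - 0.4)) / 4
  hand_h <- -(log(0.7) + log(0.3) + log(1 - 0.9) + log(1 - 0.1)) / 4
  expect_equal(multitask_loss(pl, tl, ph, th, loss_weights(1, 1.8)),
               hand_l + 1.8 * hand_h)
  # swapping the organs together with their weights leaves the loss fixed
  expect_equal(multitask_loss(pl, tl, ph, th, loss_weights(1, 1.8)),
               multitask_loss(ph, th, pl, tl, loss_weights(1.8, 1)))
  # invalid targets are rejected
  expect_error(multitask_loss(pl, tl + 1, ph, th, loss_weights()), "0, 1")
})

test_that("engine loss agrees with the reference implementation", {
  spec <- separation_model_spec(16, base_filters = 2)
  m <- build_semi_siamese(spec, seed = 3)
  x <- random_batch(3, 256, seed = 4)
  tl <- random_batch(3, 256, seed = 5)
  th <- random_batch(3, 256, seed = 6)
  pr <- cpp_unet_predict(m$ptr, x, 8L)
  ev <- cpp_unet_eval(m$ptr, x, list(tl, th), c(1, 1.8), 8L, 0.5)
  expect_equal(ev$loss,
               multitask_loss(pr[[1]], tl, pr[[2]], th,
                              loss_weights(1, 1.8)),
               tolerance = 1e-4)
})

test_that("backpropagated gradients match finite differences along random directions", {
  spec <- separation_model_spec(16, base_filters = 2, dropout_rate = 0)
  m <- build_semi_siamese(spec, seed = 42)
  x <- random_batch(3, 256, seed = 1)
  tl <- random_batch(3, 256, seed = 2)
  th <- random_batch(3, 256, seed = 3)
  w0 <- cpp_unet_get_weights(m$ptr)
  lg <- cpp_unet_lossgrad(m$ptr, x, list(tl, th), c(1, 1.8))
  g <- lg$gradient
  lossfun <- function(w) {
    cpp_unet_set_weights(m$ptr, w)
    cpp_unet_eval(m$ptr, x, list(tl, th), c(1, 1.8), 8L, 0.5)$loss
  }
  d <- g / sqrt(sum(g^2))
  fd <- (lossfun(w0 + 1e-2 * d) - lossfun(w0 - 1e-2 * d)) / 2e-2
  expect_equal(fd, sum(g * d), tolerance = 2e-2)
  set.seed(9)
  d2 <- rnorm(length(w0)); d2 <- d2 / sqrt(sum(d2^2))
  fd2 <- (lossfun(w0 + 1e-2 * d2) - lossfun(w0 - 1e-2 * d2)) / 2e-2
  expect_equal(fd2, sum(g * d2), tolerance = 0.05)
})

test_that("training is deterministic for a fixed seed and checkpoints follow the schedule", {
  ds <- fix_dataset16()
  spec <- separation_model_spec(16, base_filters = 2)
  cfg <- train_config(epochs = 2, checkpoint_every = 2, seed = 11)
  f1 <- train_separation(build_semi_siamese(spec, seed = 11), ds,
                         config = cfg)
  f2 <- train_separation(build_semi_siamese(spec, seed = 11), ds,
                         config = cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$weights, f2$weights)
  expect_equal(vapply(f1$checkpoints, function(ck) ck$epoch, 1), 2)

  # 1 epoch with checkpoint_every > 1: no intermediate checkpoints, final
  # state still available
  cfg1 <- suppressWarnings(train_config(epochs = 1, checkpoint_every = 10,
                                        seed = 1))
  f3 <- train_separation(build_semi_siamese(spec, seed = 1), ds,
                         config = cfg1)
  expect_length(f3$checkpoints, 0)
  expect_length(f3$weights, count_parameters(f3$model))
  expect_equal(nrow(f3$history), 1)
})

test_that("training reduces the loss on a scaled-down dataset", {
  ds <- fix_dataset16()
  spec <- separation_model_spec(16, base_filters = 4)
  better <- vapply(c(21, 22, 23), function(seed) {
    cfg1 <- suppressWarnings(train_config(epochs = 1, checkpoint_every = 0,
                                          seed = seed))
    cfg10 <- train_config(epochs = 10, checkpoint_every = 10, seed = seed)
    l1 <- utils::tail(train_separation(build_semi_siamese(spec, seed),
                                       ds, config = cfg1)$history$train_loss,
                      1)
    l10 <- utils::tail(train_separation(build_semi_siamese(spec, seed),
                                        ds,
                                        config = cfg10)$history$train_loss,
                       1)
    l10 < l1
  }, TRUE)
  expect_true(all(better))
})

test_that("restored checkpoints reproduce their recorded validation loss", {
  ds <- fix_dataset16()
  sp <- ds$split
  spec <- separation_model_spec(16, base_filters = 2)
  cfg <- train_config(epochs = 4, checkpoint_every = 2, seed = 13)
  fit <- train_separation(build_semi_siamese(spec, seed = 13), ds,
                          config = cfg)
  ck <- fit$checkpoints[[1]]
  m2 <- build_semi_siamese(spec, seed = 99)
  cpp_unet_set_weights(m2$ptr, ck$weights)
  tens <- eitsep:::training_tensors(ds, sp)
  ev <- cpp_unet_eval(m2$ptr, tens$x_val, list(tens$lung_val,
                                               tens$heart_val),
                      c(1, 1), cfg$batch_size, 0.5)
  expect_equal(ev$loss, ck$val_loss, tolerance = 1e-6)
})

test_that("fine-tuning resumes from the requested checkpoint with new weights", {
  ds <- fix_dataset16()
  spec <- separation_model_spec(16, base_filters = 2)
  cfg <- train_config(epochs = 4, checkpoint_every = 2, seed = 17)
  fit <- train_separation(build_semi_siamese(spec, seed = 17), ds,
                          config = cfg)
  ft <- fine_tune_from_checkpoint(fit, loss_weights(1, 1.8), ds,
                                  from_epoch = 2, extra_epochs = 2)
  expect_equal(max(ft$history$epoch), 4 + 2 - 2)  # resumed at 2, ran 2 more
  expect_true(any(ft$history$phase == "finetune_wheart_1.8"))
  expect_error(fine_tune_from_checkpoint(fit, loss_weights(1, 1.5), ds,
                                         from_epoch = 3),
               "no checkpoint")

  # unit-weight fine-tuning is a plain continuation of the same objective
  ft1 <- fine_tune_from_checkpoint(fit, loss_weights(1, 1), ds,
                                   from_epoch = 2, extra_epochs = 1)
  expect_true(any(ft1$history$phase == "finetune_wheart_1"))
})

test_that("dual U-Net training produces tagged per-network histories", {
  ds <- fix_dataset16()
  spec <- separation_model_spec(16, base_filters = 2)
  cfg <- train_config(epochs = 2, checkpoint_every = 2, seed = 19)
  dfit <- train_separation(build_dual_unet(spec, seed = 19), ds,
                           config = cfg)
  h <- tidy(dfit)
  expect_setequal(unique(h$network), c("unet_lung", "unet_heart"))
  expect_equal(nrow(h), 4)
  pr <- predict(dfit, eitsep:::split_matrix(ds, "mixed", ds$split$test))
  expect_named(pr, c("lung", "heart"))
})
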