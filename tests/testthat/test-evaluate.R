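# Dice / MAE metric contracts and report arithmetic.

test_that("dice handles identical, disjoint, partial and empty masks", {
  a <- matrix(0, 3, 3); a[c(1, 2, 4, 5)] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 3, 3); b[c(8, 9)] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 2, overlap 2 -> 2*2 / (4+2)
  c3 <- matrix(0, 3, 3); c3[c(1, 2)] <- 1
  expect_equal(dice(a, c3), 2 * 2 / (4 + 2), tolerance = 1e-4)
  expect_equal(round(dice(a, c3), 4), 0.6667)
  # empty-mask conventions
  z <- matrix(0, 3, 3)
  expect_equal(dice(z, z), 1)
  expect_equal(dice(a, z), 0)
  expect_error(dice(a, matrix(0, 2, 2)), "shapes")
})

test_that("dice is symmetric and invariant under a common permutation", {
  set.seed(5)
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  expect_equal(dice(a, b), dice(b, a))
  perm <- sample(64)
  ap <- matrix(as.vector(a)[perm], 8); bp <- matrix(as.vector(b)[perm], 8)
  expect_equal(dice(ap, bp), dice(a, b))
})

test_that("mae matches hand arithmetic and metric axioms", {
  x <- matrix(runif(16), 4)
  expect_equal(mae(x, x), 0)
  expect_equal(mae(x + 0.03, x), 0.03)
  g <- matrix(c(0.1, 0, 0.3, 0), 2)
  expect_equal(mae(g, matrix(0, 2, 2)), 0.1)
  # triangle inequality and identity of indiscernibles
  set.seed(6)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  cmat <- matrix(runif(16), 4)
  expect_lte(mae(a, cmat), mae(a, b) + mae(b, cmat) + 1e-12)
  expect_gt(mae(a, b), 0)
})

test_that("identity-oracle evaluation returns exactly 100% Dice and 0% MAE", {
  ds <- fix_dataset16()
  sp <- ds$split
  idx <- sp$test
  targets <- list(lung = eitsep:::split_matrix(ds, "lung", idx),
                  heart = eitsep:::split_matrix(ds, "heart", idx))
  # a fit whose predictions are the targets themselves
  registerS3method("predict", "eitsep_oracle_fit",
                   function(object, newdata, ...) targets,
                   envir = asNamespace("stats"))
  oracle <- structure(list(config = list(batch_size = 8)),
                      class = c("eitsep_oracle_fit", "eitsep_fit"))
  mr <- evaluate_model(oracle, ds, sp, model_label = "oracle")
  expect_equal(mr$dice_percent, c(100, 100))
  expect_equal(mr$mae_percent, c(0, 0))
  expect_equal(mr$n_test, rep(length(idx), 2))
})

test_that("a constant-zero model degenerates as expected", {
  ds <- fix_dataset16()
  sp <- ds$split
  idx <- sp$test
  zeros <- list(
    lung = matrix(0, length(idx), ds$grid_size^2),
    heart = matrix(0, length(idx), ds$grid_size^2))
  registerS3method("predict", "eitsep_zero_fit",
                   function(object, newdata, ...) zeros,
                   envir = asNamespace("stats"))
  mr <- evaluate_model(
    structure(list(config = list(batch_size = 8)),
              class = c("eitsep_zero_fit", "eitsep_fit")),
    ds, sp, model_label = "zero")
  # zero predictions: Dice 0 against non-empty targets; MAE equals the mean
  # target intensity
  expect_equal(mr$dice_percent, c(0, 0))
  tmean <- c(mean(eitsep:::split_matrix(ds, "lung", idx)),
             mean(eitsep:::split_matrix(ds, "heart", idx)))
  expect_equal(mr$mae_percent, 100 * tmean, tolerance = 1e-10)
})

test_that("comparison reports recompute the published improvement arithmetic", {
  mk <- function(label, dice_h, dice_l, mae_h, mae_l) {
    out <- tibble::tibble(model = label, organ = c("lung", "heart"),
                          dice_percent = c(dice_l, dice_h),
                          mae_percent = c(mae_l, mae_h), n_test = 120L)
    class(out) <- c("eitsep_metrics", class(out))
    out
  }
  semi <- mk("semi", 93.56, 98.84, 2.67, 2.67)
  base <- mk("dual", 88.38, 96.65, 3.36, 5.85)
  rep <- render_report(semi, base)
  get <- function(metric, organ) {
    rep$improvement[rep$metric == metric & rep$organ == organ]
  }
  expect_equal(get("DICE (%)", "heart"), 5.18)
  expect_equal(get("DICE (%)", "lung"), 2.19)
  expect_equal(get("MAE (%)", "heart"), 0.69)
  expect_equal(get("MAE (%)", "lung"), 3.18)
  # self-comparison: all improvements vanish
  self_rep <- render_report(semi, semi)
  expect_true(all(self_rep$improvement == 0))
  # markdown rendering carries 8 metric cells (2 metrics x 2 organs x 2 models)
  md <- format_report(rep)
  expect_length(md, 2 + 4)
})

test_that("trained-model evaluation produces the full report layout", {
  ds <- fix_dataset16()
  spec <- separation_model_spec(16, base_filters = 2)
  cfg <- train_config(epochs = 1, checkpoint_every = 0, seed = 23)
  fit <- train_separation(build_semi_siamese(spec, seed = 23), ds,
                          config = cfg)
  dfit <- train_separation(build_dual_unet(spec, seed = 23), ds,
                           config = cfg)
  mr <- evaluate_model(fit, ds)
  mb <- evaluate_model(dfit, ds)
  rep <- render_report(mr, mb)
  expect_equal(nrow(rep), 4)
  expect_equal(length(rep$model) + length(rep$baseline), 8)
})
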