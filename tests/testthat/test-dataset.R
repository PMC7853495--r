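test_that("scenario grid has the right size, order and endpoints", {
  sc <- enumerate_scenarios(40, 30)
  expect_equal(nrow(sc), 1200)
  expect_equal(range(sc$lung_radius), c(0.3, 0.6))
  expect_equal(range(sc$heart_radius), c(0.1, 0.3))
  # row-major with lung radius as the outer loop
  expect_equal(sc$lung_radius[1:30], rep(0.3, 30))
  expect_equal(sc$heart_radius[1:30], seq(0.1, 0.3, length.out = 30))

  expect_equal(nrow(enumerate_scenarios(1, 1)), 1)
  expect_equal(enumerate_scenarios(1, 1)$lung_radius, 0.3)
  expect_equal(enumerate_scenarios(1, 1)$heart_radius, 0.1)
  sc22 <- enumerate_scenarios(2, 2)
  expect_equal(sort(unique(sc22$lung_radius)), c(0.3, 0.6))
  expect_equal(sort(unique(sc22$heart_radius)), c(0.1, 0.3))
})

test_that("split fractions follow the 10% test then 90/10 train/val rule", {
  sp <- split_dataset(1200, seed = 42)
  expect_equal(length(sp$test), 120)
  expect_equal(length(sp$val), 108)
  expect_equal(length(sp$train), 972)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:1200)
  # determinism
  sp2 <- split_dataset(1200, seed = 42)
  expect_identical(sp[c("train", "val", "test")],
                   sp2[c("train", "val", "test")])
  # different seed shuffles differently
  sp3 <- split_dataset(1200, seed = 43)
  expect_false(identical(sp$test, sp3$test))
  expect_error(split_dataset(5), "too small")
})

test_that("an organ-free scene produces an identically zero triplet", {
  ctx <- fix_ctx16()
  sc <- phantom_scene(0.45, 0.2, organs_present = character(0))
  tr <- generate_triplet(sc, ctx)
  expect_true(all(tr$mixed$grid == 0))
  expect_true(all(tr$lung_target$grid == 0))
  expect_true(all(tr$heart_target$grid == 0))
})

test_that("heart targets peak near the heart centre; organ signs oppose", {
  ctx <- fix_ctx16()
  for (hr in c(0.15, 0.25)) {
    tr <- generate_triplet(phantom_scene(0.45, hr), ctx)
    g <- tr$heart_target$grid
    N <- nrow(g)
    xs <- seq(-1 + 1 / N, 1 - 1 / N, length.out = N)
    peak <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, ]
    p <- c(xs[peak[1]], xs[peak[2]])
    d_heart <- sqrt(sum((p - c(0, 0.15))^2))
    d_lungs <- min(sqrt(sum((p - c(-0.5, 0))^2)),
                   sqrt(sum((p - c(0.5, 0))^2)))
    expect_lt(d_heart, d_lungs)
    # heart is a conductivity increase, lungs a decrease
    expect_gt(max(g), 0)
    expect_lt(min(tr$lung_target$grid), 0)
    expect_gt(max(g), abs(min(g)))
    lt <- tr$lung_target$grid
    expect_gt(abs(min(lt)), max(lt))
  }
})

test_that("dataset bundles hold 3 images per scene and regenerate bit-identically", {
  ctx <- fix_ctx16()
  scenes <- enumerate_scenarios(5, 2)
  ds1 <- build_dataset(scenes, ctx)
  expect_equal(dim(ds1$images$mixed), c(10, 16, 16))
  expect_equal(length(ds1$images) * nrow(scenes), 30)  # 3 x scenes images
  ds2 <- build_dataset(scenes, ctx)
  expect_identical(ds1$images, ds2$images)
})

test_that("normalization statistics come from the training split only", {
  ds <- fix_dataset16()
  sp <- ds$split
  mask <- ds$disk_mask
  tr_vals <- unlist(lapply(ds$images, function(a) {
    apply(a[sp$train, , , drop = FALSE], 1, function(g) g[mask])
  }))
  # after normalization the training split spans exactly [0, 1]
  expect_equal(min(tr_vals), 0)
  expect_equal(max(tr_vals), 1)
  expect_equal(ds$normalization$stats_source, "train_split_global")
  # outside-disk pixels stay exactly zero
  outside <- apply(ds$images$mixed, 1, function(g) g[!mask])
  expect_true(all(outside == 0))
})

test_that("dataset bundles survive a save/load round trip", {
  ds <- fix_dataset16()
  path <- file.path(tempdir(), "ds.rds")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_identical(back$images, ds$images)
  expect_true(file.exists(file.path(tempdir(), "ds_scenes.csv")))
})
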