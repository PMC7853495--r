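test_that("ridge shrinkage: operator norm decreases monotonically in lambda", {
  hom <- fix_homog512()
  norms <- vapply(c(0.01, 0.05, 0.2, 1),
                  function(l) norm(build_reconstructor(hom$jac, "noser",
                                                       l)$B, "2"), 1)
  expect_true(all(diff(norms) < 0))
})

test_that("reconstructor is deterministic and identity prior recovers the row space", {
  hom <- fix_homog512()
  b1 <- build_reconstructor(hom$jac, "noser", 0.05)
  b2 <- build_reconstructor(hom$jac, "noser", 0.05)
  expect_identical(b1$B, b2$B)

  mesh <- build_disk_mesh(100, 16, 0.5)
  jac <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)), fix_protocol())
  op <- build_reconstructor(jac, "identity", 1e-6)
  set.seed(1)
  x_row <- as.numeric(t(jac$J) %*% rnorm(nrow(jac$J)))   # row-space vector
  xhat <- as.numeric(op$B %*% (jac$J %*% x_row))
  expect_lt(sqrt(sum((xhat - x_row)^2) / sum(x_row^2)), 1e-4)
})

test_that("difference reconstruction is linear and zero at zero difference", {
  mesh <- fix_mesh512()
  hom <- fix_homog512()
  op <- build_reconstructor(hom$jac, "noser", 0.05)
  v1 <- forward_solve(mesh,
                      assign_conductivity(mesh, phantom_scene(0.5, 0.2)),
                      fix_protocol())
  expect_equal(reconstruct_difference(op, hom$v, hom$v),
               numeric(nrow(mesh$elements)))
  # homogeneity to machine precision (plain-vector interface, zero reference)
  dv <- v1$value - hom$v$value
  zero <- numeric(length(dv))
  x1 <- reconstruct_difference(op, dv, zero)
  expect_identical(reconstruct_difference(op, 2 * dv, zero), 2 * x1)
  # additivity
  set.seed(4)
  dv2 <- rnorm(length(dv), sd = stats::sd(dv))
  xs <- reconstruct_difference(op, dv + dv2, zero)
  expect_equal(xs, x1 + reconstruct_difference(op, dv2, zero),
               tolerance = 1e-12)
})

test_that("a small central inclusion is localized near its true position", {
  mesh <- fix_mesh512()
  hom <- fix_homog512()
  op <- build_reconstructor(hom$jac, "noser", 0.05)
  sc <- phantom_scene(0.45, 0.15, heart_center = c(0.15, 0),
                      organs_present = "heart")
  v <- forward_solve(mesh, assign_conductivity(mesh, sc), fix_protocol())
  im <- rasterize(reconstruct_difference(op, v, hom$v), mesh, 64)
  peak <- which(abs(im$grid) == max(abs(im$grid)), arr.ind = TRUE)[1, ]
  xs <- seq(-1 + 1 / 64, 1 - 1 / 64, length.out = 64)
  expect_lt(sqrt((xs[peak[1]] - 0.15)^2 + xs[peak[2]]^2), 0.2)
})

test_that("mixed-scene reconstruction differs from the single-organ sum by a bounded residual", {
  mesh <- fix_mesh512()
  hom <- fix_homog512()
  op <- build_reconstructor(hom$jac, "noser", 0.05)
  rec <- function(organs) {
    sc <- phantom_scene(0.5, 0.2, organs_present = organs)
    v <- forward_solve(mesh, assign_conductivity(mesh, sc), fix_protocol())
    reconstruct_difference(op, v, hom$v)
  }
  xm <- rec(c("lungs", "heart")); xl <- rec("lungs"); xh <- rec("heart")
  res <- sqrt(sum((xm - xl - xh)^2) / sum(xm^2))
  expect_gt(res, 1e-6)   # the mixing is not additively separable
  expect_lt(res, 1)      # but the interaction term stays bounded
})

test_that("rasterization maps element values onto disk pixels exactly", {
  mesh <- fix_mesh512()
  cvals <- rep(3.5, nrow(mesh$elements))
  im <- rasterize(cvals, mesh, 32)
  expect_true(all(im$grid[im$disk_mask] == 3.5))
  expect_true(all(im$grid[!im$disk_mask] == 0))
  im0 <- rasterize(numeric(nrow(mesh$elements)), mesh, 32)
  expect_true(all(im0$grid == 0))
})

test_that("rasterizing a two-element mesh partitions the grid along the shared edge", {
  # hand-built square split along the main diagonal; disk pixels only
  mesh2 <- structure(list(
    nodes = rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
    elements = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    boundary_edges = NULL,
    electrode_edges = list(), n_electrodes = 0L,
    areas = c(2, 2),
    centroids = rbind(c(1 / 3, -1 / 3), c(-1 / 3, 1 / 3))),
    class = "eit_mesh")
  im <- rasterize(c(10, 20), mesh2, 16)
  xs <- seq(-1 + 1 / 16, 1 - 1 / 16, length.out = 16)
  px <- outer(xs, rep(1, 16)); py <- outer(rep(1, 16), xs)
  inside <- im$disk_mask
  below <- inside & (py < px)   # strictly below the diagonal: element 1
  above <- inside & (py > px)
  expect_true(all(im$grid[below] == 10))
  expect_true(all(im$grid[above] == 20))
})

test_that("affine normalization has exact range, exact inverse, and clamps out-of-sample values", {
  set.seed(3)
  imgs <- lapply(1:4, function(i) eit_image(matrix(rnorm(16^2), 16)))
  nz <- normalize_affine(imgs)
  vals <- unlist(lapply(nz$images, function(im) im$grid[im$disk_mask]))
  expect_equal(min(vals), 0)
  expect_equal(max(vals), 1)
  back <- denormalize_affine(nz$images[[2]], nz$record)
  expect_equal(back$grid, imgs[[2]]$grid, tolerance = 1e-12)
  # out-of-sample image with a larger range is clamped, and the rate logged
  wild <- eit_image(matrix(rnorm(16^2, sd = 10), 16))
  nz2 <- normalize_affine(list(wild), record = nz$record)
  v2 <- nz2$images[[1]]$grid[nz2$images[[1]]$disk_mask]
  expect_true(all(v2 >= 0 & v2 <= 1))
  expect_gt(nz2$record$clamp_rate, 0)
})

test_that("degenerate constant intensities are rejected", {
  imgs <- list(eit_image(matrix(1, 16, 16)))
  expect_error(normalize_affine(imgs), "degenerate")
})
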