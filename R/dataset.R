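# Phantom scene enumeration, triplet generation, dataset packaging & splits.

#' Enumerate phantom scenes on a radius grid
#'
#' Cartesian grid of `lung_steps` equally spaced lung radii over
#' \[0.3, 0.6\] by `heart_steps` heart radii over \[0.1, 0.3\], in row-major
#' order with the lung radius as the outer loop.  The full-scale sweep uses
#' 40 x 30 = 1200 scenes.
#'
#' @param lung_steps,heart_steps Grid sizes (>= 1).
#' @return A tibble with `scene_id`, `lung_radius`, `heart_radius`.
#' @examples
#' nrow(enumerate_scenarios(40, 30))  # 1200
#' @export
enumerate_scenarios <- function(lung_steps = 40L, heart_steps = 30L) {
  stopifnot(lung_steps >= 1, heart_steps >= 1)
  lr <- seq(0.3, 0.6, length.out = lung_steps)
  hr <- seq(0.1, 0.3, length.out = heart_steps)
  out <- tibble::tibble(
    lung_radius = rep(lr, each = heart_steps),
    heart_radius = rep(hr, times = lung_steps))
  out$scene_id <- seq_len(nrow(out))
  out[, c("scene_id", "lung_radius", "heart_radius")]
}

#' Build the shared simulation context for a dataset sweep
#'
#' Constructs, once, everything the per-scene pipeline reuses: the mesh, the
#' adjacent protocol, the homogeneous reference voltages, the background
#' Jacobian, the reconstruction operator and the pixel-to-element map.
#'
#' @param n_elements Target mesh element count (around 2000 at full scale,
#'   around 500 for reduced runs).
#' @param grid_size Output image resolution (256 full scale, 64 reduced).
#' @param n_electrodes,electrode_coverage Mesh electrode layout.
#' @param contact_impedance,amplitude Forward-model settings.
#' @param lambda,prior Reconstruction settings (see [build_reconstructor()]).
#' @return A list of class `eit_sim_context`.
#' @export
make_sim_context <- function(n_elements = 2000L, grid_size = 256L,
                             n_electrodes = 16L, electrode_coverage = 0.5,
                             contact_impedance = 0.01, amplitude = 1,
                             lambda = 0.05, prior = "noser") {
  mesh <- build_disk_mesh(n_elements, n_electrodes, electrode_coverage)
  protocol <- make_adjacent_protocol(n_electrodes, amplitude)
  sigma_ref <- rep(1, nrow(mesh$elements))
  v_ref <- forward_solve(mesh, sigma_ref, protocol, contact_impedance)
  jac <- compute_jacobian(mesh, sigma_ref, protocol, contact_impedance)
  op <- build_reconstructor(jac, prior, lambda)
  pix_map <- pixel_element_map(mesh, grid_size)
  structure(list(mesh = mesh, protocol = protocol, v_ref = v_ref,
                 jacobian = jac, reconstructor = op, pix_map = pix_map,
                 grid_size = grid_size, contact_impedance = contact_impedance,
                 config = list(n_elements = n_elements,
                               grid_size = grid_size,
                               n_electrodes = n_electrodes,
                               electrode_coverage = electrode_coverage,
                               contact_impedance = contact_impedance,
                               amplitude = amplitude, lambda = lambda,
                               prior = prior)),
            class = "eit_sim_context")
}

#' Generate one (mixed, lungs-only, heart-only) image triplet
#'
#' Runs the full pipeline for the three variants of a scene — both organs,
#' lungs only, heart only — each as forward solve, linearized difference
#' reconstruction against the homogeneous reference, and rasterization.
#'
#' @param scene A `phantom_scene`, or a row of [enumerate_scenarios()] output
#'   (a list with `lung_radius` and `heart_radius`).
#' @param ctx An `eit_sim_context` (built once, shared across scenes).
#' @param noise_sd Standard deviation of optional additive Gaussian
#'   measurement noise (default 0 = noise free).
#' @return List of class `sample_triplet` with `mixed`, `lung_target` and
#'   `heart_target` (`eit_image`s) and the scene.
#' @export
generate_triplet <- function(scene, ctx, noise_sd = 0) {
  stopifnot(inherits(ctx, "eit_sim_context"))
  if (!inherits(scene, "phantom_scene")) {
    scene <- phantom_scene(lung_radius = scene$lung_radius,
                           heart_radius = scene$heart_radius)
  }
  variant <- function(organs) {
    sc <- scene
    sc$organs_present <- intersect(scene$organs_present, organs)
    sig <- assign_conductivity(ctx$mesh, sc)
    v <- tryCatch(
      forward_solve(ctx$mesh, sig, ctx$protocol, ctx$contact_impedance),
      error = function(e) stop("forward solve failed for scene (lung ",
                               scene$lung_radius, ", heart ",
                               scene$heart_radius, "): ",
                               conditionMessage(e)))
    if (noise_sd > 0) v$value <- v$value + stats::rnorm(nrow(v), 0, noise_sd)
    x <- reconstruct_difference(ctx$reconstructor, v, ctx$v_ref)
    rasterize(x, ctx$mesh, ctx$grid_size, ctx$pix_map)
  }
  structure(list(mixed = variant(c("lungs", "heart")),
                 lung_target = variant("lungs"),
                 heart_target = variant("heart"),
                 scene = scene),
            class = "sample_triplet")
}

#' Generate and package a full phantom dataset
#'
#' Runs [generate_triplet()] for every scene and collects the raw (not yet
#' normalized) images into dense arrays.  Three images are produced per
#' scene, so the full-scale 1200-scene sweep solves 3600 inverse problems.
#' The pipeline is deterministic for a fixed configuration (and fixed
#' `seed` when measurement noise is enabled).
#'
#' @param scenes Tibble from [enumerate_scenarios()].
#' @param ctx An `eit_sim_context`.
#' @param noise_sd Additive measurement-noise standard deviation (default 0).
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @param progress Print progress every 100 scenes.
#' @return An object of class `eit_dataset`: list with `images` (list of
#'   `mixed`, `lung`, `heart` arrays of dim `n x N x N`), `scenes`,
#'   `disk_mask`, `config`, `seed`, and (after [normalize_dataset()]) the
#'   normalization record and split.
#' @export
build_dataset <- function(scenes, ctx, noise_sd = 0, seed = 42L,
                          progress = FALSE) {
  n <- nrow(scenes)
  N <- ctx$grid_size
  arr <- function() array(0, c(n, N, N))
  images <- list(mixed = arr(), lung = arr(), heart = arr())
  if (noise_sd > 0) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  for (i in seq_len(n)) {
    tr <- generate_triplet(scenes[i, ], ctx, noise_sd)
    images$mixed[i, , ] <- tr$mixed$grid
    images$lung[i, , ]  <- tr$lung_target$grid
    images$heart[i, , ] <- tr$heart_target$grid
    if (progress && i %% 100 == 0) message("scene ", i, "/", n)
  }
  disk_mask <- attr(ctx$pix_map, "disk_mask")
  structure(list(images = images, scenes = scenes, disk_mask = disk_mask,
                 grid_size = N, config = ctx$config, noise_sd = noise_sd,
                 seed = seed, normalization = NULL, split = NULL),
            class = "eit_dataset")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed",
                                               envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Split a dataset into train / validation / test triplet indices
#'
#' Seeded shuffle of the scene indices; the first `test_fraction` become the
#' held-out test set, then `val_fraction` of the remainder become the
#' validation set and the rest the training set (floor convention, remainder
#' to train).  Triplets are never split across sets.
#'
#' @param x An `eit_dataset` or a scene count.
#' @param test_fraction Fraction held out for testing (default 0.10).
#' @param val_fraction Fraction of the remainder used for validation
#'   (default 0.10).
#' @param seed Shuffle seed (default 42, recorded in the result).
#' @return A list of class `eit_split` with integer index vectors `train`,
#'   `val`, `test` (disjoint, union = all scenes).
#' @examples
#' s <- split_dataset(1200)
#' lengths(s[c("test", "val", "train")])  # 120 108 972
#' @export
split_dataset <- function(x, test_fraction = 0.10, val_fraction = 0.10,
                          seed = 42L) {
  n <- if (inherits(x, "eit_dataset")) nrow(x$scenes) else as.integer(x)
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction > 0, val_fraction < 1)
  n_test <- floor(n * test_fraction)
  n_val <- floor((n - n_test) * val_fraction)
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1) {
    stop("dataset too small for non-empty train/val/test splits")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  structure(list(test = sort(perm[seq_len(n_test)]),
                 val = sort(perm[n_test + seq_len(n_val)]),
                 train = sort(perm[(n_test + n_val + 1):n]),
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 seed = seed),
            class = "eit_split")
}

#' Normalize a dataset with training-split statistics
#'
#' Computes the global affine normalization record from all mixed and target
#' images of the *training* split only (no test leakage), applies the
#' identical map to every image of every split, clamps out-of-range values
#' to \[0, 1\], and stores record and split in the dataset.
#'
#' @param dataset An `eit_dataset`.
#' @param split An `eit_split`.
#' @return The dataset with normalized images, `normalization` record (with
#'   the observed clamp rate) and `split` attached.
#' @export
normalize_dataset <- function(dataset, split) {
  stopifnot(inherits(dataset, "eit_dataset"), inherits(split, "eit_split"))
  mask <- dataset$disk_mask
  tr <- split$train
  lo <- Inf; hi <- -Inf
  for (kind in names(dataset$images)) {
    v <- dataset$images[[kind]][tr, , , drop = FALSE]
    mv <- apply(v, 1, function(g) range(g[mask]))
    lo <- min(lo, mv[1, ]); hi <- max(hi, mv[2, ])
  }
  if (hi <= lo) stop("degenerate dataset: affine normalization undefined")
  clamped <- 0; total <- 0
  for (kind in names(dataset$images)) {
    a <- dataset$images[[kind]]
    for (i in seq_len(dim(a)[1])) {
      g <- a[i, , ]
      v <- (g[mask] - lo) / (hi - lo)
      clamped <- clamped + sum(v < 0 | v > 1); total <- total + length(v)
      g[mask] <- pmin(1, pmax(0, v))
      a[i, , ] <- g
    }
    dataset$images[[kind]] <- a
  }
  dataset$normalization <- list(lo = lo, hi = hi,
                                stats_source = "train_split_global",
                                clamp_rate = clamped / total)
  dataset$split <- split
  dataset
}

#' Convenience pipeline: enumerate, simulate, split and normalize
#'
#' @param lung_steps,heart_steps Scene grid (see [enumerate_scenarios()]).
#' @param ctx Simulation context; built from `...` via [make_sim_context()]
#'   when omitted.
#' @param split_seed Shuffle seed for [split_dataset()].
#' @param ... Passed to [make_sim_context()] when `ctx` is missing.
#' @return A normalized `eit_dataset` with split attached.
#' @export
prepare_dataset <- function(lung_steps = 40L, heart_steps = 30L, ctx = NULL,
                            split_seed = 42L, ...) {
  if (is.null(ctx)) ctx <- make_sim_context(...)
  scenes <- enumerate_scenarios(lung_steps, heart_steps)
  ds <- build_dataset(scenes, ctx)
  sp <- split_dataset(ds, seed = split_seed)
  normalize_dataset(ds, sp)
}

#' Persist / load a dataset bundle
#'
#' The bundle is stored with `saveRDS` (R-native serialization); the scene
#' table is additionally exported as plain CSV next to it for inspection.
#'
#' @param dataset An `eit_dataset`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  utils::write.csv(dataset$scenes,
                   sub("\\.rds$", "_scenes.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

# images of one split as a (n, npix) matrix for the network
split_matrix <- function(dataset, kind, idx) {
  a <- dataset$images[[kind]][idx, , , drop = FALSE]
  dim(a) <- c(length(idx), dataset$grid_size^2)
  a
}

#' @export
print.eit_dataset <- function(x, ...) {
  cat("<eit_dataset>", nrow(x$scenes), "scenes x 3 images,",
      x$grid_size, "x", x$grid_size, "px",
      if (!is.null(x$normalization)) "(normalized)" else "(raw)", "\n")
  if (!is.null(x$split)) {
    cat("  split train/val/test:", length(x$split$train),
        length(x$split$val), length(x$split$test), "\n")
  }
  invisible(x)
}
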