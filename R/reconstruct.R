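# One-step regularized linearized difference imaging and rasterization.

#' Build a one-step linearized reconstruction operator
#'
#' Forms the explicit linear map `B = (J'J + lambda^2 R)^-1 J'` from voltage
#' differences to element conductivity changes.  `R` is either the identity
#' (plain Tikhonov ridge) or the NOSER prior `diag(J'J)^0.5`, which weights
#' the penalty by local sensitivity and partially compensates the low
#' sensitivity of central elements.
#'
#' @param jac An `eit_jacobian` from [compute_jacobian()].
#' @param regularization_kind `"noser"` (default) or `"identity"`.
#' @param lambda Non-negative regularization hyperparameter (default 0.05).
#' @return An object of class `eit_reconstructor` holding the dense matrix
#'   `B` (elements x measurements) and the regularization settings.
#' @export
build_reconstructor <- function(jac, regularization_kind = c("noser",
                                                             "identity"),
                                lambda = 0.05) {
  stopifnot(inherits(jac, "eit_jacobian"), lambda >= 0,
            all(is.finite(jac$J)))
  regularization_kind <- match.arg(regularization_kind)
  J <- jac$J
  JtJ <- crossprod(J)
  d <- if (regularization_kind == "noser") sqrt(diag(JtJ)) else
    rep(1, ncol(J))
  M <- JtJ + lambda^2 * diag(d, ncol(J))
  ch <- tryCatch(chol(M), error = function(e) {
    stop("regularized normal matrix is numerically singular; ",
         "use lambda > 0 (J'J is rank-deficient whenever there are more ",
         "elements than measurements)")
  })
  B <- backsolve(ch, backsolve(ch, t(J), transpose = TRUE))
  structure(list(B = B, regularization_kind = regularization_kind,
                 lambda = lambda, n_measurements = nrow(J)),
            class = "eit_reconstructor")
}

#' Reconstruct a difference image in element space
#'
#' Applies the reconstruction operator to the voltage difference between a
#' scene frame and a reference frame: `x = B (v_scene - v_reference)`.  The
#' map is linear in both voltage arguments.
#'
#' @param op An `eit_reconstructor`.
#' @param v_scene,v_reference `eit_voltages` tibbles (or plain numeric
#'   vectors) sharing the same protocol ordering.
#' @return Numeric vector of per-element conductivity changes.
#' @export
reconstruct_difference <- function(op, v_scene, v_reference) {
  stopifnot(inherits(op, "eit_reconstructor"))
  v1 <- if (is.numeric(v_scene)) v_scene else v_scene$value
  v0 <- if (is.numeric(v_reference)) v_reference else v_reference$value
  if (length(v1) != length(v0) || length(v1) != op$n_measurements) {
    stop("voltage frame length does not match the reconstruction operator")
  }
  as.numeric(op$B %*% (v1 - v0))
}

# map each pixel centre of an N x N grid over [-1,1]^2 to its containing
# element (NA outside the unit disk; nearest centroid where the polygonal
# mesh boundary leaves a sliver of disk uncovered)
pixel_element_map <- function(mesh, grid_size) {
  N <- grid_size
  xs <- seq(-1 + 1 / N, 1 - 1 / N, length.out = N)
  px <- rep(xs, times = N)   # pixel (ix, iy) at linear index (iy-1)*N + ix
  py <- rep(xs, each = N)
  inside_disk <- px^2 + py^2 <= 1
  map <- rep(NA_integer_, N * N)
  el <- mesh$elements
  nodes <- mesh$nodes
  for (e in seq_len(nrow(el))) {
    p1 <- nodes[el[e, 1], ]; p2 <- nodes[el[e, 2], ]; p3 <- nodes[el[e, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- which(xs >= xr[1] & xs <= xr[2])
    iy <- which(xs >= yr[1] & xs <= yr[2])
    if (!length(ix) || !length(iy)) next
    cand <- as.vector(outer(ix, (iy - 1L) * N, `+`))
    cand <- cand[is.na(map[cand]) & inside_disk[cand]]
    if (!length(cand)) next
    qx <- px[cand]; qy <- py[cand]
    d1 <- (p2[1] - p1[1]) * (qy - p1[2]) - (p2[2] - p1[2]) * (qx - p1[1])
    d2 <- (p3[1] - p2[1]) * (qy - p2[2]) - (p3[2] - p2[2]) * (qx - p2[1])
    d3 <- (p1[1] - p3[1]) * (qy - p3[2]) - (p1[2] - p3[2]) * (qx - p3[1])
    eps <- -1e-12
    hit <- d1 >= eps & d2 >= eps & d3 >= eps   # CCW triangles
    map[cand[hit]] <- e
  }
  stray <- which(inside_disk & is.na(map))
  if (length(stray)) {
    for (q in stray) {
      map[q] <- which.min((mesh$centroids[, 1] - px[q])^2 +
                          (mesh$centroids[, 2] - py[q])^2)
    }
  }
  attr(map, "n_fallback") <- length(stray)
  attr(map, "disk_mask") <- matrix(inside_disk, N, N)
  map
}

#' Rasterize an element-space image onto a square pixel grid
#'
#' Each pixel whose centre lies inside the unit disk takes the value of the
#' mesh element containing that centre (nearest-element fallback for disk
#' pixels outside the polygonal mesh hull); pixels outside the disk are
#' exactly zero.
#'
#' @param element_image Numeric vector, one value per mesh element.
#' @param mesh An `eit_mesh`.
#' @param grid_size Pixels per side (e.g. 256 at full scale, 64 for reduced
#'   runs).
#' @param pix_map Optional precomputed [pixel_element_map()] (reused across
#'   many rasterizations of the same mesh/grid).
#' @return An object of class `eit_image`: list with `grid` (N x N matrix),
#'   logical `disk_mask`, and `meta`.
#' @export
rasterize <- function(element_image, mesh, grid_size, pix_map = NULL) {
  stopifnot(length(element_image) == nrow(mesh$elements))
  if (is.null(pix_map)) pix_map <- pixel_element_map(mesh, grid_size)
  N <- grid_size
  g <- numeric(N * N)
  inside <- !is.na(pix_map)
  g[inside] <- element_image[pix_map[inside]]
  eit_image(matrix(g, N, N), attr(pix_map, "disk_mask"))
}

#' Construct a pixel image on the unit disk
#'
#' @param grid N x N numeric matrix; entries outside `disk_mask` are forced
#'   to zero.
#' @param disk_mask N x N logical matrix (TRUE inside the disk); computed
#'   from pixel-centre radii when omitted.
#' @param meta Optional metadata list.
#' @return An `eit_image`.
#' @export
eit_image <- function(grid, disk_mask = NULL, meta = list()) {
  N <- nrow(grid)
  stopifnot(ncol(grid) == N)
  if (is.null(disk_mask)) {
    xs <- seq(-1 + 1 / N, 1 - 1 / N, length.out = N)
    disk_mask <- outer(xs, xs, function(x, y) x^2 + y^2 <= 1)
  }
  grid[!disk_mask] <- 0
  structure(list(grid = grid, disk_mask = disk_mask, meta = meta),
            class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  cat("<eit_image>", nrow(x$grid), "x", ncol(x$grid),
      sprintf("range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' Global affine intensity normalization
#'
#' Maps intensities through the single affine transform
#' `x -> (x - lo) / (hi - lo)` where `(lo, hi)` is the global min/max over a
#' set of statistics images (in the dataset pipeline: all mixed and target
#' images of the training split).  The identical map is applied to every
#' image; values falling outside \[0, 1\] (possible for images not in the
#' statistics set) are clamped and the clamp rate is recorded.  Pixels
#' outside the disk stay exactly zero.
#'
#' @param images List of `eit_image` objects to normalize.
#' @param record Optional existing normalization record (from a previous
#'   call); when omitted the statistics are computed from `images`
#'   themselves.
#' @param stats_source Label recorded with the statistics (only
#'   `"train_split_global"` is defined).
#' @return List with `images` (normalized), and `record` (list with `lo`,
#'   `hi`, `stats_source`, `clamp_rate` of this application).
#' @export
normalize_affine <- function(images, record = NULL,
                             stats_source = "train_split_global") {
  stats_source <- match.arg(stats_source)
  if (is.null(record)) {
    vals <- vapply(images, function(im) range(im$grid[im$disk_mask]),
                   numeric(2))
    record <- list(lo = min(vals[1, ]), hi = max(vals[2, ]),
                   stats_source = stats_source)
    if (record$hi <= record$lo) {
      stop("degenerate dataset: all intensities identical, affine ",
           "normalization undefined")
    }
  }
  clamped <- 0; total <- 0
  out <- lapply(images, function(im) {
    g <- im$grid
    v <- (g[im$disk_mask] - record$lo) / (record$hi - record$lo)
    clamped <<- clamped + sum(v < 0 | v > 1)
    total <<- total + length(v)
    g[im$disk_mask] <- pmin(1, pmax(0, v))
    eit_image(g, im$disk_mask, im$meta)
  })
  record$clamp_rate <- clamped / max(total, 1)
  list(images = out, record = record)
}

#' Invert an affine normalization record
#'
#' Recovers original intensities from a normalized image (exact up to any
#' clamping that occurred).
#'
#' @param image A normalized `eit_image`.
#' @param record The normalization record from [normalize_affine()].
#' @return An `eit_image` on the original intensity scale.
#' @export
denormalize_affine <- function(image, record) {
  g <- image$grid
  g[image$disk_mask] <- g[image$disk_mask] * (record$hi - record$lo) +
    record$lo
  eit_image(g, image$disk_mask, image$meta)
}
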