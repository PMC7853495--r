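#' Build a structured triangular mesh of the unit disk with boundary electrodes
#'
#' Constructs a deterministic polar mesh of the unit-radius disk: concentric
#' rings at radii `i/nr` with `s * i` nodes on ring `i` (`s` a multiple of the
#' electrode count), triangulated between rings by an angular two-pointer
#' merge.  The outer ring carries `electrode_count` evenly spaced electrodes,
#' each covering `electrode_coverage` of the inter-electrode pitch and
#' centred at angles `2*pi*k / electrode_count` starting at angle 0.
#'
#' The construction is fully deterministic: identical arguments give
#' byte-identical meshes.  Triangles are oriented counter-clockwise.
#'
#' @param target_element_count Requested number of triangles (>= 64).  The
#'   realized count is the nearest achievable `s * nr^2` and is guaranteed to
#'   lie within +/-30% of the request.
#' @param electrode_count Number of boundary electrodes (default 16).
#' @param electrode_coverage Fraction of the inter-electrode pitch covered by
#'   each electrode, in (0, 1).  Values >= 1 would make neighbouring
#'   electrodes touch and raise an error.
#' @return An object of class `eit_mesh`: a list with `nodes` (n x 2),
#'   `elements` (m x 3 counter-clockwise node indices), `boundary_edges`,
#'   `electrode_edges` (list of per-electrode edge matrices, ordered
#'   counter-clockwise starting at angle 0), plus precomputed element
#'   `areas` and `centroids`.
#' @examples
#' m <- build_disk_mesh(256, 16, 0.5)
#' nrow(m$elements)
#' @export
build_disk_mesh <- function(target_element_count, electrode_count = 16L,
                            electrode_coverage = 0.5) {
  stopifnot(target_element_count >= 64, electrode_count >= 4)
  if (electrode_coverage <= 0 || electrode_coverage >= 1) {
    stop("electrode_coverage must lie in (0, 1): at 1 neighbouring ",
         "electrodes touch (geometry error)")
  }
  E <- as.integer(electrode_count)

  # choose s (nodes-per-ring increment, multiple of E) and ring count nr
  best <- NULL
  for (mult in 1:4) {
    s <- mult * E
    nr <- max(2L, as.integer(round(sqrt(target_element_count / s))))
    for (cand in unique(c(nr - 1L, nr, nr + 1L))) {
      if (cand < 2L) next
      cnt <- s * cand^2
      if (is.null(best) || abs(cnt - target_element_count) < best$err) {
        best <- list(s = s, nr = cand, err = abs(cnt - target_element_count))
      }
    }
  }
  s <- best$s; nr <- best$nr
  n_elem <- s * nr^2
  if (abs(n_elem - target_element_count) > 0.3 * target_element_count) {
    stop("no achievable element count within 30% of the target")
  }

  # nodes: centre, then rings inside-out; ring i has s*i nodes at radius i/nr
  ring_start <- integer(nr)  # index of first node of ring i
  nodes <- matrix(0, 1 + s * nr * (nr + 1) / 2, 2)
  pos <- 2L
  for (i in seq_len(nr)) {
    ring_start[i] <- pos
    ni <- s * i
    ang <- 2 * pi * (seq_len(ni) - 1L) / ni
    r <- i / nr
    nodes[pos:(pos + ni - 1L), ] <- cbind(r * cos(ang), r * sin(ang))
    pos <- pos + ni
  }

  elements <- matrix(0L, n_elem, 3)
  ne <- 0L
  # centre fan
  for (j in seq_len(s)) {
    ne <- ne + 1L
    elements[ne, ] <- c(1L, ring_start[1] + j - 1L,
                        ring_start[1] + (j %% s))
  }
  # two-pointer angular merge between consecutive rings
  for (i in seq_len(nr - 1L)) {
    na <- s * i; nb <- s * (i + 1L)
    a0 <- ring_start[i]; b0 <- ring_start[i + 1L]
    ai <- 0L; bi <- 0L
    while (ai < na || bi < nb) {
      adv_b <- bi < nb && (ai == na || (bi + 1) / nb <= (ai + 1) / na)
      if (adv_b) {
        ne <- ne + 1L
        elements[ne, ] <- c(a0 + (ai %% na), b0 + (bi %% nb),
                            b0 + ((bi + 1L) %% nb))
        bi <- bi + 1L
      } else {
        ne <- ne + 1L
        elements[ne, ] <- c(a0 + (ai %% na), b0 + (bi %% nb),
                            a0 + ((ai + 1L) %% na))
        ai <- ai + 1L
      }
    }
  }
  stopifnot(ne == n_elem)

  # enforce counter-clockwise orientation
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  sa <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  flip <- sa < 0
  if (any(flip)) {
    tmp <- elements[flip, 2]
    elements[flip, 2] <- elements[flip, 3]
    elements[flip, 3] <- tmp
  }

  # outer boundary ring and electrodes
  nb_out <- s * nr
  o0 <- ring_start[nr]
  bnd <- cbind(o0 + (seq_len(nb_out) - 1L),
               o0 + (seq_len(nb_out) %% nb_out))
  per <- nb_out %/% E                       # boundary edges per pitch
  w <- max(1L, as.integer(round(electrode_coverage * per)))
  if (w >= per) {
    stop("electrode_coverage too large: electrodes would overlap on this mesh")
  }
  electrode_edges <- vector("list", E)
  for (k in seq_len(E)) {
    centre <- (k - 1L) * per                # boundary node index (0-based)
    first <- centre - w %/% 2L
    idx <- ((first + seq_len(w) - 1L) %% nb_out) + 1L
    electrode_edges[[k]] <- bnd[idx, , drop = FALSE]
  }

  area <- abs(sa) / 2
  centroids <- (p1 + p2 + p3) / 3

  structure(list(
    nodes = nodes, elements = elements, boundary_edges = bnd,
    electrode_edges = electrode_edges, n_electrodes = E,
    areas = area, centroids = centroids,
    params = list(target = target_element_count, s = s, nr = nr,
                  coverage = electrode_coverage)
  ), class = "eit_mesh")
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat("<eit_mesh>", nrow(x$nodes), "nodes,", nrow(x$elements), "elements,",
      x$n_electrodes, "electrodes\n")
  invisible(x)
}

#' Write a mesh as Triangle-style plain-text .node/.ele files
#'
#' Electrode metadata is not part of the Triangle dialect and is not written.
#'
#' @param mesh An `eit_mesh`.
#' @param basename Path prefix; `<basename>.node` and `<basename>.ele` are
#'   created.
#' @return `basename`, invisibly.
#' @export
write_mesh <- function(mesh, basename) {
  n <- nrow(mesh$nodes)
  node_lines <- c(sprintf("%d 2 0 0", n),
                  sprintf("%d %.17g %.17g", seq_len(n),
                          mesh$nodes[, 1], mesh$nodes[, 2]))
  writeLines(node_lines, paste0(basename, ".node"))
  m <- nrow(mesh$elements)
  ele_lines <- c(sprintf("%d 3 0", m),
                 sprintf("%d %d %d %d", seq_len(m), mesh$elements[, 1],
                         mesh$elements[, 2], mesh$elements[, 3]))
  writeLines(ele_lines, paste0(basename, ".ele"))
  invisible(basename)
}

#' Read a Triangle-style .node/.ele pair written by [write_mesh()]
#'
#' @inheritParams write_mesh
#' @return A list with `nodes` and `elements` matrices (no electrode data).
#' @export
read_mesh <- function(basename) {
  nd <- utils::read.table(paste0(basename, ".node"), skip = 1)
  el <- utils::read.table(paste0(basename, ".ele"), skip = 1)
  list(nodes = as.matrix(nd[, 2:3]),
       elements = matrix(as.integer(as.matrix(el[, 2:4])), nrow(el)))
}
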