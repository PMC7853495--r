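# Complete-electrode-model FEM forward solver and adjoint sensitivity.
#
# Linear (P1) triangular elements on the unit disk.  The CEM system couples
# node potentials u (N unknowns) with electrode potentials U (L unknowns):
#
#   [ K(sigma) + A_z   A_w ] [u]   [0]
#   [ A_w'             A_d ] [U] = [I]
#
# where K is the conductivity-weighted stiffness matrix, A_z, A_w, A_d are
# the contact-impedance boundary terms, and I holds the injected electrode
# currents.  The potential gauge is fixed by grounding the centre node.

# geometric assembly structure, independent of conductivity
fem_structure <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  area <- mesh$areas
  # P1 basis gradients: grad phi_i = (b_i, c_i)
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) /
       (2 * area)
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) /
        (2 * area)
  # local stiffness entries S_ij = area * (b_i b_j + c_i c_j), 9 per element
  svals <- matrix(0, m, 9)
  ii <- matrix(0L, m, 9); jj <- matrix(0L, m, 9)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    svals[, k] <- area * (b[, i] * b[, j] + cc[, i] * cc[, j])
    ii[, k] <- el[, i]; jj[, k] <- el[, j]
  }
  list(ii = as.vector(ii), jj = as.vector(jj), svals = svals,
       grad_b = b, grad_c = cc, n_nodes = nrow(mesh$nodes))
}

# sparse CEM system matrix for a conductivity field; ground_node pins the gauge
cem_matrix <- function(mesh, fs, sigma, contact_impedance, ground_node = 1L) {
  N <- fs$n_nodes
  E <- mesh$n_electrodes
  z <- contact_impedance
  xi <- as.vector(fs$svals * sigma)   # recycles sigma down rows
  ti <- fs$ii; tj <- fs$jj; tx <- xi
  for (l in seq_len(E)) {
    ed <- mesh$electrode_edges[[l]]
    len <- sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                         mesh$nodes[ed[, 2], , drop = FALSE])^2))
    n1 <- ed[, 1]; n2 <- ed[, 2]
    # 1-D mass matrix on the electrode edges (1/z scaling)
    ti <- c(ti, n1, n2, n1, n2)
    tj <- c(tj, n1, n2, n2, n1)
    tx <- c(tx, len / 3 / z, len / 3 / z, len / 6 / z, len / 6 / z)
    # coupling to the electrode potential
    ul <- N + l
    ti <- c(ti, n1, n2, rep(ul, 2 * length(len)))
    tj <- c(tj, rep(ul, 2 * length(len)), n1, n2)
    tx <- c(tx, rep(-len / 2 / z, 2), rep(-len / 2 / z, 2))
    # electrode self term |E_l| / z
    ti <- c(ti, ul); tj <- c(tj, ul); tx <- c(tx, sum(len) / z)
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N + E, N + E))
  # gauge: ground one interior node
  A[ground_node, ] <- 0
  A[, ground_node] <- 0
  A[ground_node, ground_node] <- 1
  A
}

#' Solve the EIT forward problem (complete electrode model)
#'
#' Assembles and solves the CEM finite-element system for every injection of
#' the protocol and evaluates all measurement pairs.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity vector (all positive), e.g. from
#'   [assign_conductivity()].
#' @param protocol An `eit_protocol`.
#' @param contact_impedance Uniform electrode contact impedance (default
#'   0.01, arbitrary units).
#' @return A tibble of class `eit_voltages`: the protocol rows plus a
#'   `value` column of measured voltages `U[meas_pos] - U[meas_neg]`.
#' @examples
#' mesh <- build_disk_mesh(256, 16, 0.5)
#' prot <- make_adjacent_protocol(16)
#' v <- forward_solve(mesh, rep(1, nrow(mesh$elements)), prot)
#' @export
forward_solve <- function(mesh, sigma, protocol, contact_impedance = 0.01) {
  sol <- cem_solve(mesh, sigma, protocol, contact_impedance)
  v <- sol$U[cbind(protocol$meas_pos, protocol$injection)] -
       sol$U[cbind(protocol$meas_neg, protocol$injection)]
  out <- tibble::as_tibble(protocol)
  out$value <- as.numeric(v)
  class(out) <- c("eit_voltages", class(out))
  out
}

# full CEM solve: returns node potentials (N x n_inj) and electrode
# potentials (E x n_inj)
cem_solve <- function(mesh, sigma, protocol, contact_impedance) {
  stopifnot(inherits(mesh, "eit_mesh"),
            length(sigma) == nrow(mesh$elements))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity must be strictly positive and finite")
  }
  E <- mesh$n_electrodes
  if (attr(protocol, "electrode_count") != E) {
    stop("protocol electrode count does not match the mesh")
  }
  fs <- fem_structure(mesh)
  A <- cem_matrix(mesh, fs, sigma, contact_impedance)
  inj <- unique(as.data.frame(protocol[, c("injection", "src", "sink",
                                           "amplitude")]))
  inj <- inj[order(inj$injection), ]
  N <- fs$n_nodes
  rhs <- matrix(0, N + E, nrow(inj))
  rhs[cbind(N + inj$src, seq_len(nrow(inj)))] <- inj$amplitude
  rhs[cbind(N + inj$sink, seq_len(nrow(inj)))] <- -inj$amplitude
  X <- tryCatch(as.matrix(Matrix::solve(A, rhs)),
                error = function(e) stop("singular CEM system (check that ",
                                         "conductivities are positive): ",
                                         conditionMessage(e)))
  if (any(!is.finite(X))) stop("non-finite forward solution")
  list(u = X[seq_len(N), , drop = FALSE],
       U = X[N + seq_len(E), , drop = FALSE], fs = fs)
}

#' Sensitivity (Jacobian) of all measurements to element conductivities
#'
#' Computes the adjoint-method Jacobian `J[i, e] = d(measurement i) /
#' d(sigma_e)` at the given background field.  For the adjacent protocol the
#' adjoint field of each measurement pair equals the drive field of the
#' injection sourced at the same electrode, so the 16 forward solutions
#' suffice: `J[i, e] = -area_e * grad(u_drive) . grad(u_meas) / amplitude`.
#'
#' @inheritParams forward_solve
#' @param sigma Background conductivity field (homogeneous all-ones for the
#'   standard difference-imaging pipeline).
#' @return An object of class `eit_jacobian`: list with dense matrix `J`
#'   (measurement rows x elements), the `protocol`, and the background field.
#' @export
compute_jacobian <- function(mesh, sigma, protocol, contact_impedance = 0.01) {
  sol <- cem_solve(mesh, sigma, protocol, contact_impedance)
  fs <- sol$fs
  el <- mesh$elements
  # per-element gradient of each drive solution
  gx <- fs$grad_b[, 1] * sol$u[el[, 1], ] + fs$grad_b[, 2] * sol$u[el[, 2], ] +
        fs$grad_b[, 3] * sol$u[el[, 3], ]
  gy <- fs$grad_c[, 1] * sol$u[el[, 1], ] + fs$grad_c[, 2] * sol$u[el[, 2], ] +
        fs$grad_c[, 3] * sol$u[el[, 3], ]
  amp <- protocol$amplitude[1]
  # adjoint for measurement pair (a, a+1) = drive solution of injection a
  ik <- protocol$injection
  ia <- protocol$meas_pos
  J <- -t(mesh$areas * (gx[, ik] * gx[, ia] + gy[, ik] * gy[, ia])) / amp
  structure(list(J = J, protocol = protocol, background = sigma,
                 contact_impedance = contact_impedance),
            class = "eit_jacobian")
}
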