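# Physics properties of the complete-electrode-model forward solver.

test_that("reciprocity holds for homogeneous and heterogeneous fields", {
  mesh <- fix_mesh512()
  prot <- fix_protocol()
  fields <- list(
    rep(1, nrow(mesh$elements)),
    assign_conductivity(mesh, phantom_scene(0.5, 0.25)))
  for (sigma in fields) {
    v <- forward_solve(mesh, sigma, prot)
    vm <- matrix(NA_real_, 16, 16)
    vm[cbind(v$injection, v$meas_pos)] <- v$value
    rel <- abs(vm - t(vm)) / pmax(abs(vm), abs(t(vm)))
    expect_lt(max(rel, na.rm = TRUE), 1e-8)
  }
})

test_that("CEM scaling law: sigma -> c*sigma with z -> z/c scales v by 1/c", {
  mesh <- fix_mesh512()
  prot <- fix_protocol()
  sigma <- assign_conductivity(mesh, phantom_scene(0.5, 0.25))
  v1 <- forward_solve(mesh, sigma, prot, contact_impedance = 0.01)
  cc <- 2.5
  v2 <- forward_solve(mesh, cc * sigma, prot, contact_impedance = 0.01 / cc)
  expect_equal(v2$value, v1$value / cc, tolerance = 1e-10)
})

test_that("homogeneous disk voltages converge under mesh refinement", {
  prot <- fix_protocol()
  m1 <- build_disk_mesh(1024, 16, 0.5)
  m4 <- build_disk_mesh(4096, 16, 0.5)
  v1 <- forward_solve(m1, rep(1, nrow(m1$elements)), prot)
  v4 <- forward_solve(m4, rep(1, nrow(m4$elements)), prot)
  rel <- sqrt(sum((v1$value - v4$value)^2) / sum(v4$value^2))
  expect_lt(rel, 0.02)
})

test_that("degenerate conductivities are rejected with a diagnostic", {
  mesh <- fix_mesh512()
  prot <- fix_protocol()
  sig <- rep(1, nrow(mesh$elements))
  expect_error(forward_solve(mesh, sig * 0, prot), "positive")
  expect_error(forward_solve(mesh, sig[-1], prot))
})

test_that("adjoint Jacobian matches finite differences on sampled columns", {
  mesh <- fix_mesh512()
  prot <- fix_protocol()
  hom <- fix_homog512()
  h <- 1e-6
  set.seed(7)
  for (e in sample(nrow(mesh$elements), 5)) {
    sp <- hom$sigma; sp[e] <- sp[e] + h
    fd <- (forward_solve(mesh, sp, prot)$value - hom$v$value) / h
    expect_lt(max(abs(fd - hom$jac$J[, e])) / max(abs(fd)), 0.01)
  }
})

test_that("Jacobian respects the mesh's rotational symmetry", {
  mesh <- fix_mesh512()
  hom <- fix_homog512()
  J <- hom$jac$J
  prot <- fix_protocol()
  # rotate every element by one electrode spacing and find its image
  th <- 2 * pi / 16
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot_cent <- mesh$centroids %*% t(R)
  img <- vapply(seq_len(nrow(rot_cent)), function(e) {
    which.min((mesh$centroids[, 1] - rot_cent[e, 1])^2 +
              (mesh$centroids[, 2] - rot_cent[e, 2])^2)
  }, 1L)
  # rotating an element and shifting drive + measurement indices by one
  # electrode leaves the sensitivity unchanged
  row_of <- function(k, a) which(prot$injection == k & prot$meas_pos == a)
  set.seed(11)
  rows <- sample(nrow(prot), 25)
  for (r in rows) {
    k2 <- prot$injection[r] %% 16 + 1
    a2 <- prot$meas_pos[r] %% 16 + 1
    r2 <- row_of(k2, a2)
    if (!length(r2)) next   # shifted pair touches the shifted drive
    es <- sample(nrow(mesh$elements), 10)
    expect_equal(abs(J[r2, img[es]]), abs(J[r, es]), tolerance = 1e-6)
  }
})

test_that("the Jacobian is a linear map (zero perturbation maps to zero)", {
  hom <- fix_homog512()
  expect_equal(as.numeric(hom$jac$J %*% numeric(ncol(hom$jac$J))),
               numeric(nrow(hom$jac$J)))
})
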