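# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 512-element mesh + protocol + homogeneous solve, reused by physics tests
fix_mesh512 <- function() fixture("mesh512", function() {
  build_disk_mesh(512, 16, 0.5)
})

fix_protocol <- function() fixture("protocol", function() {
  make_adjacent_protocol(16, 1)
})

fix_homog512 <- function() fixture("homog512", function() {
  mesh <- fix_mesh512()
  sigma <- rep(1, nrow(mesh$elements))
  list(sigma = sigma,
       v = forward_solve(mesh, sigma, fix_protocol()),
       jac = compute_jacobian(mesh, sigma, fix_protocol()))
})

# tiny 16x16 simulation context and 50-scene dataset for training tests
fix_ctx16 <- function() fixture("ctx16", function() {
  make_sim_context(n_elements = 256L, grid_size = 16L)
})

fix_dataset16 <- function() fixture("dataset16", function() {
  ctx <- fix_ctx16()
  ds <- build_dataset(enumerate_scenarios(10, 5), ctx)
  sp <- split_dataset(ds, seed = 42)
  normalize_dataset(ds, sp)
})

# random image batch helpers for engine-level tests
random_batch <- function(n, npix, seed = 1) {
  set.seed(seed)
  matrix(runif(n * npix), n)
}
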