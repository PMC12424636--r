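# Shared fixtures, built once per session and memoized. All geometry is
# generated in code; the coarse lattice keeps unit tests fast while the
# study-default mesh is reserved for the acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

epi_mat <- function() material_region(E = 1, nu = 0.3)
mus_mat <- function() material_region(E = 10, nu = 0.3)
both_mats <- function() list(epithelium = epi_mat(), muscle = mus_mat())

# ~100-node sphere for finite-difference and eigen checks
tiny_sphere <- function() memo("tiny_sphere", function()
  make_sphere_shell(0.8, 1, 0.55))

# moderate sphere for cheap solves
coarse_sphere <- function() memo("coarse_sphere", function()
  make_sphere_shell(0.8, 1, 0.3))

# coarse shell-in-lattice for unit tests (24 holes)
coarse_lattice_params <- function() geometry_params(
  shell_length = 3.4, shell_thickness = 0.18, n_rings = 3,
  n_longitudinal = 6, band_width = 0.4, band_thickness = 0.15,
  target_edge_length = 0.3)

coarse_lattice <- function() memo("coarse_lattice", function()
  make_shell_in_lattice(coarse_lattice_params()))

# capsule shell without lattice (free-growth benchmark)
coarse_capsule <- function() memo("coarse_capsule", function()
  make_shell_in_lattice(geometry_params(
    shell_length = 3, shell_thickness = 0.2, n_rings = 0,
    n_longitudinal = 0, target_edge_length = 0.3)))

# random admissible elastic deformation gradients near a stretch alpha
random_admissible_F <- function(n, alpha = 1, sd = 0.15, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- alpha * diag(3) + matrix(rnorm(9, sd = sd), 3, 3)
      if (det(F) > 0.2) return(F)
    }
  })
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# mean radial displacement of the luminal surface nodes
mean_inner_radial_disp <- function(mesh, state) {
  ids <- sort(unique(as.vector(mesh$facets$luminal)))
  X <- mesh$nodes[ids, , drop = FALSE]
  U <- state$U[ids, , drop = FALSE]
  mean(rowSums(U * X) / sqrt(rowSums(X^2)))
}
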