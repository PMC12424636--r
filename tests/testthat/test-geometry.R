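test_that("sphere shell volume matches the closed form and converges", {
  va <- 4 * pi / 3 * (1 - 0.8^3)
  s1 <- make_sphere_shell(0.8, 1, 0.2)
  err1 <- abs(sum(tet_volumes(s1)) - va) / va
  expect_lt(err1, 0.02)
  s2 <- make_sphere_shell(0.8, 1, 0.15)
  err2 <- abs(sum(tet_volumes(s2)) - va) / va
  expect_lt(err2, err1)  # refinement strictly reduces the volume error
  expect_error(make_sphere_shell(1.0, 0.8, 0.3), "inner_radius")
  expect_error(make_sphere_shell(0.8, 0.8, 0.3), "inner_radius")
})

test_that("bare shell has no muscle and a fully covered boundary split", {
  m <- coarse_capsule()
  expect_true(all(m$region == "epithelium"))
  expect_equal(hole_patches(m)$n_holes, 0L)
  bf <- nrow(m$facets$luminal) + nrow(m$facets$external)
  expect_gt(nrow(m$facets$luminal), 0)
  expect_length(validate_mesh(m), 0)
  # capsule wall volume against constructive geometry (coarse fixture:
  # faceting deficit dominates, tightened at default resolution below)
  va <- capsule_shell_volume(geometry_params(
    shell_length = 3, shell_thickness = 0.2, n_rings = 0,
    n_longitudinal = 0, target_edge_length = 0.3))
  expect_lt(abs(sum(tet_volumes(m)) - va) / va, 0.05)
})

test_that("lattice mesh has both regions and the analytic hole count", {
  m <- coarse_lattice()
  expect_setequal(unique(m$region), c("epithelium", "muscle"))
  expect_length(validate_mesh(m), 0)
  hp <- hole_patches(m)
  expect_equal(hp$n_holes, expected_hole_count(coarse_lattice_params()))
  # epithelial wall volume against constructive geometry, at the coarse
  # fixture resolution and tightened at the default study resolution
  va <- capsule_shell_volume(coarse_lattice_params())
  vm <- deformed_volume(m, NULL, region = "epithelium")
  expect_lt(abs(vm - va) / va, 0.05)
  md <- acc_default_mesh()
  vad <- capsule_shell_volume(geometry_params())
  vmd <- deformed_volume(md, NULL, region = "epithelium")
  expect_lt(abs(vmd - vad) / vad, 0.02)
  expect_equal(hole_patches(md)$n_holes, 48L)
})

test_that("study defaults give 48 holes and ~40% muscle coverage", {
  p <- geometry_params()
  expect_equal(expected_hole_count(p), 48L)
  m <- coarse_lattice()
  os <- epithelial_outer_surface(m)
  tri_area <- function(nodes, f) {
    e1 <- nodes[f[, 2], , drop = FALSE] - nodes[f[, 1], , drop = FALSE]
    e2 <- nodes[f[, 3], , drop = FALSE] - nodes[f[, 1], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  a <- tri_area(m$nodes, os$faces)
  cov <- sum(a[os$covered]) / sum(a)
  expect_gt(cov, 0.2)
  expect_lt(cov, 0.6)
})

test_that("infeasible lattice parameters are rejected with diagnostics", {
  expect_error(geometry_params(target_edge_length = 0.3, band_width = 0.2),
               "resolve")
  # bands so wide they leave no gaps
  expect_error(make_shell_in_lattice(geometry_params(
    shell_length = 3, n_rings = 6, n_longitudinal = 4,
    band_width = 0.9, target_edge_length = 0.25)), "overlap|no gaps")
})

test_that("mesh generation is deterministic for identical parameters", {
  p <- coarse_lattice_params()
  m1 <- make_shell_in_lattice(p)
  m2 <- make_shell_in_lattice(p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$cells, m2$cells)
  expect_identical(m1$facets, m2$facets)
})

test_that("validate_mesh reports constructed violations", {
  m <- coarse_sphere()
  expect_length(validate_mesh(m), 0)
  # inverted cell
  bad <- m
  bad$cells[5, ] <- bad$cells[5, c(2, 1, 3, 4)]
  d <- validate_mesh(bad)
  expect_true(any(grepl("negative or zero", d)))
  expect_true(any(grepl("5", d)))
  # luminal facet on a muscle cell
  ml <- coarse_lattice()
  bad2 <- ml
  own <- bad2$meta$luminal_owner
  bad2$region[own[1]] <- "muscle"
  d2 <- validate_mesh(bad2)
  expect_true(any(grepl("non-epithelium", d2)))
  # duplicated node (non-conforming interface)
  bad3 <- m
  bad3$nodes <- rbind(bad3$nodes, bad3$nodes[1, ])
  bad3$cells[1, 1] <- nrow(bad3$nodes)
  d3 <- validate_mesh(bad3)
  expect_true(any(grepl("duplicated node", d3)))
})
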