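test_that("aspect ratio reads length over mid-section width", {
  # capsule whose luminal surface has length 3 and diameter 1
  h <- 0.2
  m <- make_shell_in_lattice(geometry_params(
    shell_length = 3 * (2 * (1 - h)) / 1 + 2 * h,  # inner AR = 3
    shell_thickness = h, n_rings = 0, n_longitudinal = 0,
    target_edge_length = 0.25))
  pts <- luminal_points(m)
  expect_equal(aspect_ratio(pts), 3, tolerance = 1e-6)
  # sphere: unity by symmetry
  s <- coarse_sphere()
  expect_equal(aspect_ratio(luminal_points(s)), 1, tolerance = 1e-6)
  # a ratio is scale-invariant: uniform isotropic growth leaves it unchanged
  g <- 1.8
  u_growth <- as.vector(t((g - 1) * m$nodes))
  expect_equal(aspect_ratio(luminal_points(m, u_growth)),
               aspect_ratio(pts), tolerance = 1e-10)
  expect_error(aspect_ratio(matrix(0, 2, 3)), "degenerate")
})

test_that("thickness of the undeformed shell equals its construction value", {
  s <- coarse_sphere()
  th <- epithelial_thickness(s)
  expect_equal(th$n_missed, 0L)
  expect_equal(th$mean, 0.2, tolerance = 0.02)
  expect_lt(th$sd, 0.01)
})

test_that("nearest-point thickness is a tight lower bound on the ray reading", {
  s <- coarse_sphere()
  ray <- epithelial_thickness(s)
  near <- epithelial_thickness(s, method = "nearest")
  expect_equal(near$n_missed, 0L)
  expect_true(all(near$thickness <= ray$thickness + 1e-12))
  expect_equal(near$mean, 0.2, tolerance = 0.03)
})

test_that("thickness scales with uniform growth and shrinks under inflation", {
  s <- coarse_sphere()
  th0 <- epithelial_thickness(s)
  g <- 1.5
  u_growth <- as.vector(t((g - 1) * s$nodes))
  th1 <- epithelial_thickness(s, u_growth)
  expect_equal(th1$mean / th0$mean, g, tolerance = 0.01)
  # inflation thins the wall (thick-sphere behaviour)
  st <- newton_solve(s, list(epithelium = epi_mat()),
                     load_program(g_target = 1, p_target = -0.05,
                                  n_increments = 2))
  th2 <- epithelial_thickness(s, st)
  expect_lt(th2$mean, th0$mean)
})

test_that("protrusion amplitudes vanish at rest and are gauge-invariant", {
  m <- coarse_lattice()
  n <- nrow(m$nodes)
  pro0 <- protrusion_amplitudes(m, numeric(3 * n))
  expect_equal(nrow(pro0), expected_hole_count(coarse_lattice_params()))
  expect_equal(max(abs(pro0$amplitude)), 0)
  # rigid translation leaves amplitudes unchanged
  set.seed(9)
  u <- rnorm(3 * n, sd = 0.01)
  shift <- rep(c(0.4, -0.1, 0.25), n)
  p1 <- protrusion_amplitudes(m, u)
  p2 <- protrusion_amplitudes(m, u + shift)
  expect_equal(p1$amplitude, p2$amplitude, tolerance = 1e-10)
  # full-coverage mesh warns and returns empty
  s <- coarse_sphere()
  expect_warning(pr <- protrusion_amplitudes(s, numeric(3 * nrow(s$nodes))),
                 "no lattice holes")
  expect_equal(nrow(pr), 0L)
})

test_that("morphometry report is internally consistent at rest", {
  m <- coarse_lattice()
  rep0 <- morphometry_report(m, numeric(3 * nrow(m$nodes)))
  expect_equal(rep0$thinning_ratio, 1, tolerance = 1e-12)
  expect_equal(rep0$aspect_ratio, rep0$aspect_ratio_reference)
  expect_true(all(rep0$protrusions$amplitude == 0))
})
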