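test_that("radial oracle reproduces trivial states exactly", {
  mat <- epi_mat()
  # no load: identity map
  r0 <- solve_radial(radial_problem(0.8, 1, mat, 0, 1), n_grid = 60)
  expect_equal(max(abs(r0$r - r0$R)), 0)
  # free growth: similarity solution r = g R
  g <- 1.6
  r1 <- solve_radial(radial_problem(0.8, 1, mat, 0, g), n_grid = 60)
  expect_lt(max(abs(r1$r - g * r1$R)), 1e-8)
})

test_that("radial oracle matches the linear Lamé solution at small load", {
  mat <- epi_mat()
  q <- 1e-3
  sol <- solve_radial(radial_problem(0.8, 1, mat, -q, 1))
  u_lame <- lame_thick_sphere_u(0.8, 0.8, 1, mat$E, mat$nu, q)
  expect_lt(abs(sol$u_inner - u_lame) / u_lame, 0.01)
  # wall thins: outer displacement smaller than inner
  expect_lt(sol$u_outer, sol$u_inner)
  # grid-independence estimate is small relative to the solution
  expect_lt(sol$richardson_error, 1e-3 * abs(sol$u_inner))
})

test_that("radial oracle is pure (no state leaks between calls)", {
  mat <- epi_mat()
  p1 <- radial_problem(0.8, 1, mat, -0.05, 1)
  a <- solve_radial(p1, n_grid = 80)
  solve_radial(radial_problem(0.8, 1, mat, -0.02, 1.3), n_grid = 80)
  b <- solve_radial(p1, n_grid = 80)
  expect_identical(a$r, b$r)
})

test_that("finite-difference gradient is exact on quadratics", {
  A <- matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 4), 3, 3)
  b <- c(1, -2, 0.5)
  f <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  x0 <- c(0.3, -0.7, 1.1)
  fd <- finite_difference_gradient(f, x0, step = 1e-4)
  expect_equal(as.numeric(fd$gradient), as.numeric(A %*% x0 - b),
               tolerance = 1e-10)
  expect_lt(fd$error, 1e-9)
})
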