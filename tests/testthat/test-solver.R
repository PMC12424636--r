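test_that("residual vanishes at the unloaded reference state", {
  s <- tiny_sphere()
  n <- nrow(s$nodes)
  r <- assemble_residual(s, numeric(3 * n), list(epithelium = epi_mat()),
                         g = 1, p = 0)
  expect_equal(max(abs(r$resid)), 0)
})

test_that("follower pressure on a closed surface has zero net force", {
  s <- coarse_sphere()
  n <- nrow(s$nodes)
  r <- assemble_residual(s, numeric(3 * n), list(epithelium = epi_mat()),
                         g = 1, p = -0.05)
  fx <- matrix(r$fext, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fx))), 1e-12)
  # and nonzero locally
  expect_gt(max(abs(fx)), 1e-4)
})

test_that("internal forces are invariant under rigid translation", {
  s <- tiny_sphere()
  n <- nrow(s$nodes)
  uc <- rep(c(0.3, -0.2, 0.5), n)
  r <- assemble_residual(s, uc, list(epithelium = epi_mat()), g = 1, p = 0)
  expect_lt(max(abs(r$fint)), 1e-11)
  # constraint rows see the translation
  expect_gt(max(abs(r$resid[3 * n + 1:3])), 1)
})

test_that("assembled tangent matches finite differences of the residual", {
  s <- tiny_sphere()
  n <- nrow(s$nodes)
  mats <- list(epithelium = epi_mat())
  set.seed(4)
  u <- rnorm(3 * n, sd = 0.01)
  lag <- rnorm(6, sd = 0.01)
  g <- 1.2; p <- -0.03
  C <- rigid_constraints(s)
  K <- assemble_tangent(s, u, mats, g, p, C = C)
  z0 <- c(u, lag)
  f <- function(z) assemble_residual(
    s, list(u = z[1:(3 * n)], lagrange = z[3 * n + 1:6]), mats, g, p,
    C = C)$resid
  idx <- sort(sample(3 * n + 6, 30))
  h <- 1e-6
  scale <- max(abs(K))
  for (j in idx) {
    zp <- z0; zp[j] <- zp[j] + h
    zm <- z0; zm[j] <- zm[j] - h
    fd <- (f(zp) - f(zm)) / (2 * h)
    expect_lt(max(abs(fd - K[, j])) / scale, 1e-5)
  }
})

test_that("linearized stiffness at rest has exactly the six rigid modes", {
  s <- tiny_sphere()
  n <- nrow(s$nodes)
  K <- assemble_tangent(s, numeric(3 * n), list(epithelium = epi_mat()),
                        g = 1, p = 0)
  Kd <- as.matrix(K[1:(3 * n), 1:(3 * n)])
  ev <- eigen(Kd, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(abs(ev))
  expect_lt(ev[6] / ev[7], 1e-8)   # 6 near-zero modes, gap to the 7th
  # the rigid functionals span that null space
  C <- as.matrix(rigid_constraints(s))
  expect_equal(Matrix::rankMatrix(C)[1], 6L)
  # K annihilates explicit rigid vectors: translation and linearized rotation
  tr <- rep(c(1, 0, 0), n)
  Xc <- sweep(s$nodes, 2, colMeans(s$nodes))
  rot <- as.vector(t(cbind(-Xc[, 2], Xc[, 1], 0)))
  expect_lt(max(abs(Kd %*% tr)), 1e-10)
  expect_lt(max(abs(Kd %*% rot)), 1e-10)
})

test_that("identity load case returns zero displacement without iterating", {
  s <- tiny_sphere()
  st <- newton_solve(s, list(epithelium = epi_mat()),
                     load_program(g_target = 1, p_target = 0,
                                  n_increments = 1))
  expect_equal(max(abs(st$u)), 0)
  expect_equal(st$history$iters, 0L)
})

test_that("free uniform growth octuples the volume and stays stress-free", {
  m <- coarse_capsule()
  mats <- list(epithelium = epi_mat())
  st <- newton_solve(m, mats, load_program(g_target = 2, p_target = 0,
                                           n_increments = 4))
  vr <- deformed_volume(m, st) / deformed_volume(m)
  expect_equal(vr, 8, tolerance = 1e-8)
  expect_lt(max(cauchy_stress_norms(m, st, mats, g = 2)), 1e-6)
  # converged rigid functionals vanish
  C <- rigid_constraints(m)
  expect_lt(max(abs(C %*% st$u)), 1e-8)
})

test_that("Newton convergence is superlinear on the inflated sphere", {
  s <- coarse_sphere()
  st <- newton_solve(s, list(epithelium = epi_mat()),
                     load_program(g_target = 1, p_target = -0.05,
                                  n_increments = 2))
  for (rn in st$residual_trajectories) {
    k <- length(rn)
    expect_gte(k, 3)
    # last correction: residual drops by far more than a linear rate would
    expect_lt(rn[k] / rn[k - 1], 0.5 * rn[k - 1] / rn[k - 2] + 1e-12)
    expect_lt(rn[k] / rn[k - 1], 1e-2)
  }
  # multipliers of a self-equilibrated load stay at round-off
  load_scale <- 0.05 * 4 * pi * 0.8^2
  expect_lt(max(abs(st$lagrange)), 1e-8 * load_scale)
})

test_that("solution is gauge-independent under reference translation", {
  s <- coarse_sphere()
  prog <- load_program(g_target = 1, p_target = -0.04, n_increments = 2)
  st1 <- newton_solve(s, list(epithelium = epi_mat()), prog)
  s2 <- s
  shift <- c(0.7, -1.2, 0.4)
  s2$nodes <- sweep(s$nodes, 2, -shift)
  st2 <- newton_solve(s2, list(epithelium = epi_mat()), prog)
  expect_lt(max(abs(st2$U - st1$U)), 1e-7)
})

test_that("thick-sphere inflation converges toward the radial oracle", {
  mat <- epi_mat()
  oracle <- solve_radial(radial_problem(0.8, 1, mat, p_inner = -0.05, g = 1))
  prog <- load_program(g_target = 1, p_target = -0.05, n_increments = 3)
  errs <- vapply(list(coarse_sphere(),
                      make_sphere_shell(0.8, 1, 0.22, n_radial_layers = 2)),
                 function(s) {
                   st <- newton_solve(s, list(epithelium = mat), prog)
                   abs(mean_inner_radial_disp(s, st) - oracle$u_inner) /
                     abs(oracle$u_inner)
                 }, 0)
  expect_lt(errs[2], errs[1])  # refinement reduces the oracle mismatch
  expect_lt(errs[2], 0.05)
})
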