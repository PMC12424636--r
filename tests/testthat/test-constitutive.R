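test_that("Lamé parameters follow the engineering-constant formulas", {
  lp <- lame_from_engineering(1.0, 0.3)
  expect_equal(lp$mu, 1 / 2.6)
  expect_equal(lp$lam, 0.3 / (1.3 * 0.4))
  # linear in E
  lp10 <- lame_from_engineering(10.0, 0.3)
  expect_equal(lp10$mu, 10 * lp$mu)
  expect_equal(lp10$lam, 10 * lp$lam)
  # lambda vanishes at nu = 0
  lp0 <- lame_from_engineering(2.0, 0.0)
  expect_equal(lp0$mu, 1.0)
  expect_equal(lp0$lam, 0.0)
  expect_error(lame_from_engineering(1, 0.5), "incompressible")
  expect_error(lame_from_engineering(-1, 0.3), "positive")
})

test_that("strain energy vanishes in the reference state and under rotation", {
  mat <- epi_mat()
  expect_equal(strain_energy(diag(3), mat), 0)
  set.seed(7)
  for (k in 1:5) {
    R <- random_rotation()
    expect_lt(abs(strain_energy(R, mat)), 1e-12)
  }
})

test_that("strain energy at a uniform stretch matches the closed form", {
  a <- 1.1
  mat <- epi_mat()
  Je <- a^3
  psi_expected <- mat$mu / 2 * (3 * a^2 - 3 - 2 * log(Je)) +
    mat$lam / 2 * log(Je)^2
  expect_equal(strain_energy(a * diag(3), mat), psi_expected)
  expect_error(strain_energy(-diag(3), mat), "inadmissible")
})

test_that("first PK stress is the energy gradient and matches closed forms", {
  for (mat in list(epi_mat(), mus_mat())) {
    expect_equal(first_pk_stress(diag(3), mat), matrix(0, 3, 3))
    # isotropic stretch closed form
    a <- 1.25
    P <- first_pk_stress(a * diag(3), mat)
    p_expected <- mat$mu * (a - 1 / a) + mat$lam * 3 * log(a) / a
    expect_equal(P, p_expected * diag(3), tolerance = 1e-12)
    # finite-difference oracle at random states
    for (F in random_admissible_F(5, seed = 11 + mat$E)) {
      fd <- finite_difference_gradient(
        function(v) strain_energy(matrix(v, 3, 3), mat), as.vector(F),
        step = 1e-5)
      Pa <- first_pk_stress(F, mat)
      expect_lt(max(abs(matrix(fd$gradient, 3, 3) - Pa)) / max(abs(Pa)),
                1e-6)
    }
  }
})

test_that("stress is frame-indifferent", {
  mat <- epi_mat()
  set.seed(3)
  for (F in random_admissible_F(5, seed = 5)) {
    R <- random_rotation()
    expect_equal(strain_energy(R %*% F, mat), strain_energy(F, mat),
                 tolerance = 1e-10)
    expect_equal(first_pk_stress(R %*% F, mat), R %*% first_pk_stress(F, mat),
                 tolerance = 1e-10)
  }
})

test_that("growth split is stress-free under pure growth", {
  g <- 1.7
  dp <- deformation_point(g * diag(3), g)
  expect_equal(dp$Fe, diag(3))
  expect_equal(dp$Je, 1)
  expect_equal(strain_energy(dp$Fe, epi_mat()), 0)
  expect_equal(total_pk_stress(g * diag(3), g, epi_mat()), matrix(0, 3, 3))
})

test_that("material tangent matches finite differences of the stress", {
  mat <- epi_mat()
  g <- 1.4
  for (F in random_admissible_F(3, alpha = g, sd = 0.1, seed = 21)) {
    A <- material_tangent(F, g, mat)
    fd <- finite_difference_gradient(
      function(v) as.vector(total_pk_stress(matrix(v, 3, 3), g, mat)),
      as.vector(F), step = 1e-5)
    Afd <- array(fd$gradient, c(3, 3, 3, 3))  # [iJ, kL] column-major
    expect_lt(max(abs(A - Afd)) / max(abs(A)), 1e-5)
  }
})

test_that("tangent has major symmetry and reduces to isotropic elasticity", {
  mat <- mus_mat()
  g <- 1.3
  for (F in random_admissible_F(3, alpha = g, sd = 0.08, seed = 31)) {
    A <- material_tangent(F, g, mat)
    expect_equal(A, aperm(A, c(3, 4, 1, 2)), tolerance = 1e-12)
  }
  # at the grown stress-free state: small-strain tensor scaled by 1/g^2
  A0 <- material_tangent(g * diag(3), g, mat)
  Aiso <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (J in 1:3) for (k in 1:3) for (L in 1:3)
    Aiso[i, J, k, L] <- (mat$lam * (i == J) * (k == L) +
                           mat$mu * ((i == k) * (J == L) +
                                       (i == L) * (J == k))) / g^2
  expect_equal(A0, Aiso, tolerance = 1e-12)
})
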