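#' Convert engineering constants to Lamé parameters
#'
#' @description
#' Computes the first (shear) and second Lamé parameters from Young's modulus
#' and Poisson's ratio,
#' \deqn{\mu = \frac{E}{2(1+\nu)}, \qquad
#'       \lambda = \frac{E\nu}{(1+\nu)(1-2\nu)}.}
#' The material model in this package is compressible, so the incompressible
#' limit \eqn{\nu = 1/2} is rejected.
#'
#' @param E Young's modulus (dimensionless; stresses are nondimensionalized by
#'   the epithelial modulus).
#' @param nu Poisson's ratio, in \eqn{(-1, 1/2)}.
#' @return Named list with components `mu` and `lam`.
#' @examples
#' lame_from_engineering(1.0, 0.3)
#' @export
lame_from_engineering <- function(E, nu) {
  stopifnot(is.numeric(E), length(E) == 1L, is.numeric(nu), length(nu) == 1L)
  if (E <= 0) stop("Young's modulus E must be positive, got ", E)
  if (nu <= -1 || nu >= 0.5) {
    stop("Poisson's ratio must lie in (-1, 0.5); nu = 0.5 is the ",
         "incompressible limit, which the compressible neo-Hookean model ",
         "used here excludes. Got nu = ", nu)
  }
  list(mu = E / (2 * (1 + nu)), lam = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' Define a material region
#'
#' Bundles engineering constants with their derived Lamé parameters for one
#' tissue region (epithelium or smooth muscle).
#'
#' @inheritParams lame_from_engineering
#' @return Object of class `material_region` with fields `E`, `nu`, `mu`, `lam`.
#' @examples
#' epi <- material_region(E = 1.0, nu = 0.3)
#' mus <- material_region(E = 10.0, nu = 0.3)
#' @export
material_region <- function(E, nu) {
  lp <- lame_from_engineering(E, nu)
  structure(list(E = E, nu = nu, mu = lp$mu, lam = lp$lam),
            class = "material_region")
}

#' @export
print.material_region <- function(x, ...) {
  cat(sprintf("<material_region> E = %g, nu = %g  (mu = %g, lam = %g)\n",
              x$E, x$nu, x$mu, x$lam))
  invisible(x)
}

#' Kinematic quantities of the multiplicative growth split
#'
#' Given the total deformation gradient `F` and a scalar isotropic growth
#' factor `g`, returns the growth tensor `Fg = g I`, the elastic part
#' `Fe = F Fg^{-1} = F / g`, and the elastic volume change `Je = det(Fe)`.
#'
#' @param F 3x3 deformation gradient.
#' @param g scalar growth factor (> 0); `g = 1` means no growth, so `Fe = F`.
#' @return List with `F`, `g`, `Fg`, `Fe`, `Je`.
#' @export
deformation_point <- function(F, g = 1) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)), g > 0)
  Fe <- F / g
  list(F = F, g = g, Fg = diag(3) * g, Fe = Fe, Je = det(Fe))
}

#' Compressible neo-Hookean strain energy density
#'
#' @description
#' \deqn{\psi(F_e) = \frac{\mu}{2}\left(\mathrm{tr}(F_e^T F_e) - 3
#'   - 2\ln J_e\right) + \frac{\lambda}{2}(\ln J_e)^2, \quad J_e = \det F_e.}
#' The energy vanishes in the stress-free reference state (`Fe = I`) and is
#' frame-indifferent: it depends on `Fe` only through \eqn{F_e^T F_e} and
#' \eqn{\det F_e}.
#'
#' @param Fe 3x3 elastic deformation gradient with positive determinant.
#' @param mat a [material_region()].
#' @return Scalar energy density (per unit reference volume).
#' @export
strain_energy <- function(Fe, mat) {
  Je <- det(Fe)
  if (!is.finite(Je) || Je <= 0) {
    stop("inadmissible elastic state: det(Fe) = ", Je,
         " (element inversion)", call. = FALSE)
  }
  lJ <- log(Je)
  mat$mu / 2 * (sum(Fe * Fe) - 3 - 2 * lJ) + mat$lam / 2 * lJ^2
}

#' First Piola-Kirchhoff stress of the neo-Hookean law
#'
#' @description
#' The stress conjugate to the elastic deformation gradient,
#' \deqn{P = \partial\psi/\partial F_e
#'         = \mu (F_e - F_e^{-T}) + \lambda \ln(J_e)\, F_e^{-T}.}
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola-Kirchhoff stress tensor (w.r.t. `Fe`).
#' @export
first_pk_stress <- function(Fe, mat) {
  Je <- det(Fe)
  if (!is.finite(Je) || Je <= 0) {
    stop("inadmissible elastic state: det(Fe) = ", Je,
         " (element inversion)", call. = FALSE)
  }
  FinvT <- t(solve(Fe))
  mat$mu * (Fe - FinvT) + mat$lam * log(Je) * FinvT
}

#' Material tangent of the grown stress with respect to total F
#'
#' @description
#' The solver works with the stress per unit reference volume expressed as a
#' function of the *total* deformation gradient,
#' \eqn{P_{tot}(F) = \partial\psi(F/g)/\partial F = P(F/g)/g}. This returns its
#' consistent linearization \eqn{A = \partial P_{tot}/\partial F} as a
#' 3x3x3x3 array with index order \eqn{A[i,J,k,L]}. Hyperelasticity implies
#' the major symmetry \eqn{A_{iJkL} = A_{kLiJ}}.
#'
#' @param F 3x3 total deformation gradient.
#' @param g scalar growth factor.
#' @param mat a [material_region()].
#' @return 3x3x3x3 numeric array.
#' @export
material_tangent <- function(F, g, mat) {
  Fe <- F / g
  Je <- det(Fe)
  if (!is.finite(Je) || Je <= 0) {
    stop("inadmissible elastic state: det(Fe) = ", Je,
         " (element inversion)", call. = FALSE)
  }
  B <- solve(Fe)  # Fe^{-1}
  lJ <- log(Je)
  mu <- mat$mu; lam <- mat$lam
  A <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (J in 1:3) for (k in 1:3) for (L in 1:3) {
    A[i, J, k, L] <- mu * (i == k) * (J == L) +
      (mu - lam * lJ) * B[J, k] * B[L, i] +
      lam * B[L, k] * B[J, i]
  }
  A / g^2
}

#' Total first Piola-Kirchhoff stress with respect to F
#'
#' Chain rule of [first_pk_stress()] through the growth split:
#' \eqn{P_{tot}(F) = P(F/g)/g}. This is the stress the assembly integrates
#' against \eqn{\nabla\delta u} in the reference configuration.
#'
#' @inheritParams material_tangent
#' @return 3x3 stress tensor.
#' @export
total_pk_stress <- function(F, g, mat) {
  first_pk_stress(F / g, mat) / g
}
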