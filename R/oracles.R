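#' Define a spherically symmetric inflation/growth benchmark problem
#'
#' @param inner_radius,outer_radius shell radii (`0 < inner < outer`).
#' @param mat a [material_region()].
#' @param p_inner signed pressure on the inner surface (negative inflates,
#'   same convention as [load_program()]).
#' @param g isotropic growth factor applied to the whole shell.
#' @return object of class `radial_problem`.
#' @export
radial_problem <- function(inner_radius, outer_radius, mat,
                           p_inner = 0, g = 1) {
  stopifnot(inner_radius > 0, inner_radius < outer_radius,
            inherits(mat, "material_region"), g > 0)
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 mat = mat, p_inner = p_inner, g = g),
            class = "radial_problem")
}

#' Semi-analytic radial oracle for spherically symmetric deformation
#'
#' @description
#' Independent benchmark for the three-dimensional solver: under spherical
#' symmetry the deformation map reduces to \eqn{r(R)} with deformation
#' gradient \eqn{F = \mathrm{diag}(r', r/R, r/R)} in the spherical frame. The
#' two-point boundary-value problem (inner surface loaded by the follower
#' pressure, outer surface traction-free) is solved by minimizing the total
#' potential on a 1D grid graded toward the inner boundary: linear elements,
#' midpoint quadrature of the stored energy, the pressure entering through
#' the enclosed-volume potential \eqn{p \frac{4\pi}{3} r(R_{in})^3}, Newton
#' iteration with continuation in the load, and a Richardson check against a
#' once-refined grid.
#'
#' @param problem a [radial_problem()].
#' @param n_grid number of radial elements (default 160).
#' @param n_continuation load continuation steps (default 8).
#' @param tol Newton residual tolerance.
#' @return list with `R` (grid), `r` (deformed radii), `u_inner`, `u_outer`
#'   (radial displacements at the walls), and `richardson_error` (estimated
#'   discretization error of `u_inner`).
#' @export
solve_radial <- function(problem, n_grid = 160L, n_continuation = 8L,
                         tol = 1e-9) {
  fine <- radial_solve_grid(problem, n_grid, n_continuation, tol)
  coarse <- radial_solve_grid(problem, max(20L, n_grid %/% 2L),
                              n_continuation, tol)
  fine$richardson_error <- abs(fine$u_inner - coarse$u_inner)
  fine
}

radial_grid <- function(Rin, Rout, n) {
  s <- seq(0, 1, length.out = n + 1)
  Rin + (Rout - Rin) * (1 - (1 - s)^1.3)  # finer near the inner boundary
}

# residual of the discrete radial potential; r defined at the n+1 grid nodes
radial_residual <- function(r, Rg, mat, p, g) {
  n <- length(Rg) - 1L
  dR <- diff(Rg)
  Rm <- (Rg[-1] + Rg[-(n + 1L)]) / 2
  rm <- (r[-1] + r[-(n + 1L)]) / 2
  F1 <- diff(r) / dR
  F2 <- rm / Rm
  Fe1 <- F1 / g; Fe2 <- F2 / g
  if (any(Fe1 <= 0) || any(Fe2 <= 0)) return(NULL)
  Je <- Fe1 * Fe2^2
  lJ <- log(Je)
  mu <- mat$mu; lam <- mat$lam
  P1 <- (mu * (Fe1 - 1 / Fe1) + lam * lJ / Fe1) / g
  P2 <- (mu * (Fe2 - 1 / Fe2) + lam * lJ / Fe2) / g
  w <- 4 * pi * Rm^2 * dR
  res <- numeric(n + 1L)
  # d/dr_i of sum w * psi: F1 couples to (r_{i+1}-r_i)/dR, F2 to (r_i+r_{i+1})/2
  contrib_lo <- w * (P1 * (-1 / dR) + 2 * P2 * (0.5 / Rm))
  contrib_hi <- w * (P1 * (1 / dR) + 2 * P2 * (0.5 / Rm))
  res[-(n + 1L)] <- res[-(n + 1L)] + contrib_lo
  res[-1] <- res[-1] + contrib_hi
  res[1] <- res[1] + p * 4 * pi * r[1]^2
  res
}

radial_solve_grid <- function(problem, n, n_cont, tol) {
  Rg <- radial_grid(problem$inner_radius, problem$outer_radius, n)
  r <- Rg
  for (k in seq_len(n_cont)) {
    s <- k / n_cont
    gk <- 1 + s * (problem$g - 1)
    pk <- s * problem$p_inner
    r <- radial_newton(r, Rg, problem$mat, pk, gk, tol)
  }
  list(R = Rg, r = r,
       u_inner = r[1] - Rg[1], u_outer = r[length(r)] - Rg[length(Rg)])
}

radial_newton <- function(r, Rg, mat, p, g, tol) {
  nfree <- length(r)
  rn_prev <- Inf
  for (it in 1:60) {
    res <- radial_residual(r, Rg, mat, p, g)
    if (is.null(res)) stop("radial oracle: inadmissible state during Newton")
    rn <- sqrt(sum(res^2))
    if (rn < tol) return(r)
    # the finite-difference Jacobian limits the attainable floor; accept a
    # stalled iteration once the residual is far below discretization level
    if (rn < 1e-7 && rn > 0.5 * rn_prev) return(r)
    rn_prev <- rn
    # tridiagonal Jacobian by 3-coloured central differences
    J <- matrix(0, nfree, nfree)
    h <- 1e-7 * max(1, max(abs(r)))
    for (col in 0:2) {
      idx <- seq(col + 1L, nfree, by = 3L)
      rp <- r; rp[idx] <- rp[idx] + h
      rm <- r; rm[idx] <- rm[idx] - h
      dp <- radial_residual(rp, Rg, mat, p, g)
      dm <- radial_residual(rm, Rg, mat, p, g)
      if (is.null(dp) || is.null(dm))
        stop("radial oracle: inadmissible state in Jacobian evaluation")
      d <- (dp - dm) / (2 * h)
      for (i in idx) {
        rows <- max(1L, i - 1L):min(nfree, i + 1L)
        J[rows, i] <- d[rows]
      }
    }
    dr <- solve(J, -res)
    # damped update keeping the state admissible
    alpha <- 1
    repeat {
      rn <- r + alpha * dr
      ok <- !is.null(radial_residual(rn, Rg, mat, p, g))
      if (ok || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    r <- r + alpha * dr
  }
  stop("radial oracle: Newton did not converge")
}

#' Closed-form linear-elastic (Lamé) thick-sphere displacement
#'
#' Small-strain solution for a thick-walled sphere with internal pressure `q`
#' and traction-free outer surface:
#' \deqn{u(r) = \frac{q R_{in}^3 r}{E (R_{out}^3 - R_{in}^3)}
#'  \left[(1 - 2\nu) + (1+\nu)\frac{R_{out}^3}{2 r^3}\right].}
#'
#' @param r radius (or vector of radii) at which to evaluate.
#' @param inner_radius,outer_radius shell radii.
#' @param E,nu engineering constants.
#' @param q internal pressure magnitude (positive inflates).
#' @return radial displacement at `r`.
#' @export
lame_thick_sphere_u <- function(r, inner_radius, outer_radius, E, nu, q) {
  q * inner_radius^3 * r / (E * (outer_radius^3 - inner_radius^3)) *
    ((1 - 2 * nu) + (1 + nu) * outer_radius^3 / (2 * r^3))
}

#' Central-difference gradient with Richardson extrapolation
#'
#' Independent differentiation oracle used to verify analytic stresses and
#' tangents: central differences at steps `h` and `h/2` combined by one
#' Richardson step, with the difference between the two estimates reported as
#' the truncation-error estimate.
#'
#' @param f scalar- or vector-valued function of a numeric vector.
#' @param x evaluation point (numeric vector).
#' @param step base step size `h`.
#' @return list with `gradient` (length(f) x length(x) Jacobian, dropped to a
#'   vector for scalar `f`) and `error` (max abs difference between the two
#'   central estimates).
#' @export
finite_difference_gradient <- function(f, x, step = 1e-5) {
  central <- function(h) {
    cols <- lapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    })
    do.call(cbind, cols)
  }
  g1 <- central(step)
  g2 <- central(step / 2)
  g <- (4 * g2 - g1) / 3
  err <- max(abs(g2 - g1))
  if (nrow(g) == 1L) g <- drop(g)
  list(gradient = g, error = err)
}
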