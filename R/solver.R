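#' Load program: target growth and pressure with a linear ramp
#'
#' @description
#' The quasistatic loading schedule. At load fraction \eqn{s \in [0,1]} the
#' growth factor is \eqn{g(s) = 1 + s(g_{target} - 1)} inside the growth
#' region (the rest of the mesh keeps \eqn{g = 1}) and the luminal pressure is
#' \eqn{p(s) = s\, p_{target}}. Both are ramped linearly over
#' `n_increments` equal steps.
#'
#' Sign convention: the follower-load term uses the outward reference normal
#' of the solid on the luminal surface, which points into the lumen, so
#' *negative* `p_target` inflates the shell. The equivalent
#' `inflation_magnitude = -p_target` is carried alongside the signed value.
#'
#' @param g_target final growth factor (>0; 1 means no growth).
#' @param p_target final signed luminal pressure (negative inflates).
#' @param n_increments number of ramp increments (>= 1).
#' @param growth_region region label that grows (default `"epithelium"`).
#' @return object of class `load_program`.
#' @export
load_program <- function(g_target = 2, p_target = -0.2, n_increments = 20L,
                         growth_region = "epithelium") {
  stopifnot(g_target > 0, n_increments >= 1)
  structure(list(g_target = g_target, p_target = p_target,
                 n_increments = as.integer(n_increments),
                 growth_region = growth_region,
                 inflation_magnitude = -p_target),
            class = "load_program")
}

#' Newton solver settings
#'
#' @param newton_rel_tol residual norm tolerance relative to the first
#'   out-of-balance residual of each increment.
#' @param newton_abs_tol absolute residual norm tolerance.
#' @param max_newton_iter maximum Newton iterations per increment.
#' @param max_halvings maximum adaptive increment halvings on divergence or
#'   element inversion.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(newton_rel_tol = 1e-8, newton_abs_tol = 1e-10,
                            max_newton_iter = 25L, max_halvings = 4L) {
  stopifnot(newton_rel_tol > 0, newton_abs_tol > 0, max_newton_iter >= 1)
  structure(list(newton_rel_tol = newton_rel_tol,
                 newton_abs_tol = newton_abs_tol,
                 max_newton_iter = as.integer(max_newton_iter),
                 max_halvings = as.integer(max_halvings)),
            class = "solver_settings")
}

#' Rigid-body constraint functionals
#'
#' Six linear functionals removing the rigid modes: the summed displacement
#' \eqn{\sum_a u_a = 0} and the summed moment about the reference centroid
#' \eqn{\sum_a (X_a - \bar X) \times u_a = 0}, enforced through Lagrange
#' multipliers.
#'
#' @param mesh a `tet_mesh`.
#' @return a 6 x 3n sparse matrix (rows: 3 translations, 3 rotations).
#' @export
rigid_constraints <- function(mesh) {
  n <- nrow(mesh$nodes)
  Xc <- sweep(mesh$nodes, 2, colMeans(mesh$nodes))
  dofx <- 3 * seq_len(n) - 2; dofy <- dofx + 1; dofz <- dofx + 2
  # rows 4..6: components of sum (X - Xbar) x u
  i <- c(rep(1L, n), rep(2L, n), rep(3L, n),
         rep(4L, n), rep(4L, n), rep(5L, n), rep(5L, n),
         rep(6L, n), rep(6L, n))
  j <- c(dofx, dofy, dofz,
         dofz, dofy,  dofx, dofz,  dofy, dofx)
  x <- c(rep(1, 3 * n),
         Xc[, 2], -Xc[, 3],  Xc[, 3], -Xc[, 1],  Xc[, 1], -Xc[, 2])
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(6L, 3L * n))
}

# per-cell Lame parameter vectors from the region map
cell_material_vectors <- function(mesh, materials) {
  regs <- unique(mesh$region)
  missing <- setdiff(regs, names(materials))
  if (length(missing))
    stop("no material given for region(s): ", paste(missing, collapse = ", "))
  mu <- vapply(materials, `[[`, 1, "mu")[mesh$region]
  lam <- vapply(materials, `[[`, 1, "lam")[mesh$region]
  list(mu = unname(mu), lam = unname(lam))
}

cell_growth_vector <- function(mesh, g, growth_region) {
  ifelse(mesh$region == growth_region, g, 1)
}

as_u_vector <- function(state, n) {
  u <- if (is.list(state)) state$u else state
  if (is.matrix(u)) u <- as.vector(t(u))
  if (is.null(u)) u <- numeric(3 * n)
  stopifnot(length(u) == 3 * n)
  u
}

#' Assemble the equilibrium residual
#'
#' @description
#' The discrete weak form: internal virtual work of the grown neo-Hookean
#' stress minus the virtual work of the follower luminal pressure (pulled back
#' to the reference configuration by Nanson's formula), augmented with the six
#' rigid-mode constraint rows. The returned vector is
#' `c(f_int - f_ext + t(C) %*% lagrange, C %*% u)`.
#'
#' @param mesh a `tet_mesh`.
#' @param state a numeric displacement vector (length 3n, node-major), an
#'   n x 3 matrix, or a list with fields `u` and `lagrange`.
#' @param materials named list of [material_region()] per region label.
#' @param g scalar growth factor for the growth region.
#' @param p signed luminal pressure (negative inflates).
#' @param growth_region region that grows (default epithelium).
#' @param C optional precomputed [rigid_constraints()] matrix.
#' @return list with `resid` (length 3n + 6), `fint`, `fext`, `psi` and `Je`
#'   per cell.
#' @export
assemble_residual <- function(mesh, state, materials, g = 1, p = 0,
                              growth_region = "epithelium", C = NULL) {
  n <- nrow(mesh$nodes)
  u <- as_u_vector(state, n)
  lag <- if (is.list(state) && !is.null(state$lagrange)) state$lagrange
         else numeric(6)
  mv <- cell_material_vectors(mesh, materials)
  gc <- cell_growth_vector(mesh, g, growth_region)
  a <- asm_internal(mesh$nodes, mesh$cells, u, gc, mv$mu, mv$lam, FALSE)
  if (!is.null(a$inverted))
    stop(inverted_condition(a$inverted, a$where))
  fext <- numeric(3 * n)
  if (p != 0 && nrow(mesh$facets$luminal) > 0) {
    pr <- asm_pressure(mesh$nodes, mesh$facets$luminal, u, p, FALSE)
    fext <- pr$fext
  }
  if (is.null(C)) C <- rigid_constraints(mesh)
  ru <- a$resid - fext + as.numeric(Matrix::crossprod(C, lag))
  rc <- as.numeric(C %*% u)
  list(resid = c(ru, rc), fint = a$resid, fext = fext, psi = a$psi, Je = a$Je)
}

#' Assemble the consistent tangent (saddle-point system matrix)
#'
#' @description
#' The Jacobian of [assemble_residual()]: material plus geometric stiffness of
#' the grown hyperelastic stress, the (unsymmetric) follower-load pressure
#' stiffness, and the rigid-constraint coupling blocks
#' \eqn{[K, C^T; C, 0]}.
#'
#' @inheritParams assemble_residual
#' @param include_pressure_stiffness include the follower-load linearization
#'   (default TRUE; disabling it degrades Newton to quasi-Newton).
#' @return a `(3n+6) x (3n+6)` sparse `dgCMatrix`.
#' @export
assemble_tangent <- function(mesh, state, materials, g = 1, p = 0,
                             growth_region = "epithelium", C = NULL,
                             include_pressure_stiffness = TRUE) {
  n <- nrow(mesh$nodes)
  u <- as_u_vector(state, n)
  mv <- cell_material_vectors(mesh, materials)
  gc <- cell_growth_vector(mesh, g, growth_region)
  a <- asm_internal(mesh$nodes, mesh$cells, u, gc, mv$mu, mv$lam, TRUE)
  if (!is.null(a$inverted))
    stop(inverted_condition(a$inverted, a$where))
  ti <- a$i; tj <- a$j; tx <- a$x
  if (p != 0 && include_pressure_stiffness &&
      nrow(mesh$facets$luminal) > 0) {
    pr <- asm_pressure(mesh$nodes, mesh$facets$luminal, u, p, TRUE)
    ti <- c(ti, pr$i); tj <- c(tj, pr$j); tx <- c(tx, pr$x)
  }
  if (is.null(C)) C <- rigid_constraints(mesh)
  cs <- Matrix::summary(C)
  ndof <- 3L * n
  ti <- c(ti, ndof + cs$i, cs$j)
  tj <- c(tj, cs$j, ndof + cs$i)
  tx <- c(tx, cs$x, cs$x)
  Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                       dims = c(ndof + 6L, ndof + 6L))
}

# Six coordinate dofs whose pinning removes exactly the rigid modes (3-2-1
# scheme): node a fully held; at node b (farthest from a) the two coordinates
# off the dominant axis of ab; at node c (farthest from line ab) the dominant
# coordinate of the direction a rotation about ab would move it.
pin_dofs <- function(mesh) {
  X <- mesh$nodes
  a <- 1L
  d2 <- rowSums(sweep(X, 2, X[a, ])^2)
  b <- which.max(d2)
  e <- X[b, ] - X[a, ]; e <- e / sqrt(sum(e^2))
  dp <- sweep(X, 2, X[a, ])
  perp <- dp - outer(as.numeric(dp %*% e), e)
  cc <- which.max(rowSums(perp^2))
  kb <- which.max(abs(e))
  jb <- setdiff(1:3, kb)
  rc <- X[cc, ] - X[a, ]
  d <- c(e[2] * rc[3] - e[3] * rc[2],
         e[3] * rc[1] - e[1] * rc[3],
         e[1] * rc[2] - e[2] * rc[1])
  kc <- which.max(abs(d))
  as.integer(c(3 * a - 2:0, 3 * (b - 1) + jb, 3 * (cc - 1) + kc))
}

# Exact solver for the saddle system [K C^T; C 0] z = rhs.
#
# The displacement block is factored as a sparse Cholesky of its symmetric
# part with the six pinned dofs eliminated (SPD, handled by CHOLMOD); the
# mean/moment constraint rows C are restored exactly through a rank-12
# Woodbury correction, and the unsymmetric follower-load contribution is
# recovered by iterative refinement against the true matrix. Falls back to a
# direct unsymmetric LU of the bordered matrix if the symmetric part is not
# positive definite (e.g. past a buckling point).
make_saddle_solver <- function(C, pins) {
  ndof <- ncol(C)
  free <- setdiff(seq_len(ndof), pins)
  Cd <- as.matrix(C)
  Chat_rows <- cbind(seq_len(6L), pins)

  function(Kd, rhs_list, Kprec = Kd) {
    Ks <- Matrix::forceSymmetric((Kprec + Matrix::t(Kprec)) / 2)
    Kff <- Ks[free, free]
    # supernodal Cholesky of the symmetric part; when the follower-pressure
    # Hessian makes a few soft shell modes indefinite, a diagonal-shifted
    # factor serves as an SPD preconditioner for GMRES below.
    try_factor <- function(M) suppressWarnings(tryCatch(
      Matrix::Cholesky(M, LDL = FALSE, super = TRUE, perm = TRUE),
      error = function(e) NULL))
    ch <- try_factor(Kff)
    if (is.null(ch)) {
      shift <- 1e-3 * max(abs(Matrix::diag(Kff)))
      for (trial in 1:5) {
        ch <- try_factor(Kff + shift * Matrix::Diagonal(nrow(Kff)))
        if (!is.null(ch)) break
        shift <- 10 * shift
      }
    }
    # exact fallback: sparse LU of the pinned true matrix (no dense border
    # rows, so fill-in stays bounded) plus the same Woodbury correction
    direct_solve <- function(rs) {
      lufac <- Matrix::lu(Kd[free, free])
      Kdp <- Kd[pins, , drop = FALSE]
      Kfp <- Kd[free, pins, drop = FALSE]
      bs <- function(cu, cl) {
        u <- numeric(ndof)
        u[pins] <- cl
        u[free] <- as.numeric(Matrix::solve(lufac,
                                            cu[free] - as.numeric(Kfp %*% cl)))
        c(u, cu[pins] - as.numeric(Kdp %*% u))
      }
      D <- Cd
      D[Chat_rows] <- D[Chat_rows] - 1
      Z <- vapply(seq_len(12L), function(k) {
        if (k <= 6L) bs(D[k, ], numeric(6))
        else bs(numeric(ndof), as.numeric(seq_len(6L) == (k - 6L)))
      }, numeric(ndof + 6L))
      vt <- function(z) c(z[ndof + 1:6], as.numeric(D %*% z[seq_len(ndof)]))
      S <- diag(12)
      for (k in seq_len(12L)) S[, k] <- S[, k] + vt(Z[, k])
      lapply(rs, function(r) {
        xb <- bs(r[seq_len(ndof)], r[ndof + 1:6])
        as.numeric(xb - Z %*% solve(S, vt(xb)))
      })
    }
    if (is.null(ch)) return(direct_solve(rhs_list))
    Ksp <- Ks[pins, , drop = FALSE]

    # base solve: [Ks Chat^T; Chat 0] w = c with Chat = unit rows at pins
    base_solve <- function(cu, cl) {
      u <- numeric(ndof)
      u[pins] <- cl
      rhs <- cu[free] - as.numeric(Ks[free, pins, drop = FALSE] %*% cl)
      u[free] <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
      lam <- cu[pins] - as.numeric(Ksp %*% u)
      c(u, lam)
    }

    # Woodbury correction from Chat to the true C
    D <- Cd
    D[Chat_rows] <- D[Chat_rows] - 1
    Z <- vapply(seq_len(12L), function(k) {
      if (k <= 6L) base_solve(D[k, ], numeric(6))
      else base_solve(numeric(ndof), as.numeric(seq_len(6L) == (k - 6L)))
    }, numeric(ndof + 6L))
    Vt_of <- function(z) c(z[ndof + 1:6], as.numeric(D %*% z[seq_len(ndof)]))
    S <- diag(12)
    for (k in seq_len(12L)) S[, k] <- S[, k] + Vt_of(Z[, k])

    solve_sym <- function(r) {
      xb <- base_solve(r[seq_len(ndof)], r[ndof + 1:6])
      xb - as.numeric(Z %*% solve(S, Vt_of(xb)))
    }
    mat_vec <- function(z) {
      du <- z[seq_len(ndof)]; dl <- z[ndof + 1:6]
      c(as.numeric(Kd %*% du) + as.numeric(Matrix::crossprod(C, dl)),
        as.numeric(C %*% du))
    }
    # preconditioned GMRES on the true bordered matrix; the preconditioner
    # is exact whenever the unshifted Cholesky succeeded, so the common case
    # converges in one application
    gmres_one <- function(b) {
      bn <- sqrt(sum(b^2))
      if (bn == 0) return(numeric(length(b)))
      # inexact-Newton accuracy: far below the nonlinear tolerance, far above
      # round-off, so indefinite phases rarely need the direct fallback
      tol <- 1e-9 * bn
      x <- solve_sym(b)
      for (restart in 1:2) {
        r0 <- b - mat_vec(x)
        if (sqrt(sum(r0^2)) <= tol) return(x)
        m <- 120L
        V <- matrix(0, length(b), m + 1L)
        H <- matrix(0, m + 1L, m)
        pr0 <- solve_sym(r0)
        beta <- sqrt(sum(pr0^2))
        V[, 1] <- pr0 / beta
        y <- NULL; mj <- 0L
        for (j in seq_len(m)) {
          w <- solve_sym(mat_vec(V[, j]))
          for (i in seq_len(j)) {
            H[i, j] <- sum(w * V[, i])
            w <- w - H[i, j] * V[, i]
          }
          H[j + 1L, j] <- sqrt(sum(w^2))
          Hj <- H[seq_len(j + 1L), seq_len(j), drop = FALSE]
          rhs <- c(beta, rep(0, j))
          y <- qr.solve(Hj, rhs)
          mj <- j
          est <- sqrt(sum((rhs - Hj %*% y)^2))
          if (H[j + 1L, j] < 1e-14 * beta || est <= 1e-10 * beta) break
          V[, j + 1L] <- w / H[j + 1L, j]
        }
        x <- x + as.numeric(V[, seq_len(mj), drop = FALSE] %*% y)
      }
      if (sqrt(sum((b - mat_vec(x))^2)) <= max(tol, 1e-7 * bn)) x
      else direct_solve(list(b))[[1]]
    }
    lapply(rhs_list, gmres_one)
  }
}

inverted_condition <- function(cell, where) {
  structure(class = c("faveosim_inverted", "error", "condition"),
            list(message = paste0("element inversion in cell ", cell,
                                  " (", where, " configuration)"),
                 call = NULL, cell = cell))
}

#' Incremental Newton-Raphson solve of the growth/pressure problem
#'
#' @description
#' Ramps growth and pressure linearly to their targets over
#' `program$n_increments` increments, solving the nonlinear equilibrium at
#' each increment with a full Newton-Raphson iteration (consistent tangent,
#' sparse unsymmetric direct factorization). An increment that fails to
#' converge or inverts an element is halved adaptively up to
#' `settings$max_halvings` times.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named list of [material_region()] per region.
#' @param program a [load_program()].
#' @param settings a [solver_settings()].
#' @param store_increments keep the displacement field of every completed
#'   increment (needed for trajectory-matched comparisons and VTU series).
#' @param verbose print a one-line summary per increment to stderr.
#' @return object of class `solution_state`: fields `u` (3n vector),
#'   `U` (n x 3 matrix), `lagrange` (6 multipliers), `history` (per-increment
#'   data frame with load fraction, g, p, Newton iterations, residual norms),
#'   `residual_trajectories` (list of per-iteration residual norms),
#'   `increments` (list of per-increment states), `psi`, `Je` (per cell at the
#'   final state), and `converged`.
#' @export
newton_solve <- function(mesh, materials, program,
                         settings = solver_settings(),
                         store_increments = TRUE, verbose = FALSE) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  C <- rigid_constraints(mesh)
  lin_solve <- make_saddle_solver(C, pin_dofs(mesh))
  mv <- cell_material_vectors(mesh, materials)
  has_pressure <- program$p_target != 0 && nrow(mesh$facets$luminal) > 0

  u <- numeric(ndof)
  lag <- numeric(6)
  hist <- list(); traj <- list(); incs <- list()
  last_asm <- NULL

  load_at <- function(s) list(g = 1 + s * (program$g_target - 1),
                              p = s * program$p_target)

  solve_one <- function(s) {
    ld <- load_at(s)
    gc <- cell_growth_vector(mesh, ld$g, program$growth_region)
    rnorms <- numeric(0)
    it <- 0L
    repeat {
      a <- asm_internal(mesh$nodes, mesh$cells, u, gc, mv$mu, mv$lam, TRUE)
      if (!is.null(a$inverted)) stop(inverted_condition(a$inverted, a$where))
      fext <- numeric(ndof)
      ti <- a$i; tj <- a$j; tx <- a$x
      if (has_pressure && ld$p != 0) {
        pr <- asm_pressure(mesh$nodes, mesh$facets$luminal, u, ld$p, TRUE)
        fext <- pr$fext
        ti <- c(ti, pr$i); tj <- c(tj, pr$j); tx <- c(tx, pr$x)
      }
      ru <- a$resid - fext + as.numeric(Matrix::crossprod(C, lag))
      rc <- as.numeric(C %*% u)
      r <- c(ru, rc)
      rn <- sqrt(sum(r^2))
      rnorms <- c(rnorms, rn)
      tol <- max(settings$newton_abs_tol, settings$newton_rel_tol * rnorms[1])
      if (rn <= tol) {
        last_asm <<- a
        return(list(iters = it, rnorms = rnorms, g = ld$g, p = ld$p, s = s))
      }
      if (it >= settings$max_newton_iter)
        stop(structure(class = c("faveosim_noconv", "error", "condition"),
                       list(message = sprintf(
                         "Newton did not converge at load fraction %.4f (residual %.3e)",
                         s, rn), call = NULL)))
      # for a closed pressurized surface the follower load derives from the
      # enclosed-volume potential, so the assembled tangent is symmetric up
      # to round-off and the symmetric preconditioner is essentially exact
      Kd <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                 dims = c(ndof, ndof))
      dz <- lin_solve(Kd, list(-r))[[1]]
      u <<- u + dz[seq_len(ndof)]
      lag <<- lag + dz[ndof + 1:6]
      it <- it + 1L
    }
  }

  advance <- function(s0, s1, depth) {
    u_in <- u; lag_in <- lag
    res <- tryCatch(solve_one(s1), faveosim_inverted = function(e) e,
                    faveosim_noconv = function(e) e)
    if (inherits(res, "condition")) {
      if (depth >= settings$max_halvings)
        stop(structure(class = c("faveosim_failed", "error", "condition"),
                       list(message = paste0(
                         "increment [", signif(s0, 4), ", ", signif(s1, 4),
                         "] failed after ", depth, " halvings: ",
                         conditionMessage(res)), call = NULL)))
      u <<- u_in; lag <<- lag_in
      sm <- (s0 + s1) / 2
      advance(s0, sm, depth + 1L)
      advance(sm, s1, depth + 1L)
      return(invisible(NULL))
    }
    hist[[length(hist) + 1L]] <<- data.frame(
      s = res$s, g = res$g, p = res$p, iters = res$iters,
      resid0 = res$rnorms[1], resid = res$rnorms[length(res$rnorms)])
    traj[[length(traj) + 1L]] <<- res$rnorms
    if (store_increments)
      incs[[length(incs) + 1L]] <<- list(s = res$s, g = res$g, p = res$p,
                                         u = u, lagrange = lag)
    if (verbose)
      message(sprintf("  s=%.3f g=%.3f p=%+.4f  %d Newton iters, resid %.2e",
                      res$s, res$g, res$p, res$iters,
                      res$rnorms[length(res$rnorms)]))
    invisible(NULL)
  }

  sgrid <- seq_len(program$n_increments) / program$n_increments
  s_prev <- 0
  failure <- NULL
  for (s in sgrid) {
    bad <- tryCatch({ advance(s_prev, s, 0L); NULL },
                    faveosim_failed = function(e) e)
    if (!is.null(bad)) {
      # failure report: keep everything up to the last converged increment
      failure <- conditionMessage(bad)
      warning("newton_solve stopped early: ", failure,
              " (last converged load fraction ",
              if (length(hist)) signif(hist[[length(hist)]]$s, 4) else 0,
              ")", call. = FALSE)
      break
    }
    s_prev <- s
  }

  structure(list(u = u, U = matrix(u, ncol = 3L, byrow = TRUE),
                 lagrange = lag,
                 history = do.call(rbind, hist),
                 residual_trajectories = traj,
                 increments = incs,
                 psi = last_asm$psi, Je = last_asm$Je,
                 converged = is.null(failure), failure = failure),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<solution_state> %d increments, final g = %.3f, ",
                     "p = %+.4f, max |u| = %.4f\n"),
              nrow(h), h$g[nrow(h)], h$p[nrow(h)], max(abs(x$u))))
  invisible(x)
}

#' Deformed volume of (a region of) the mesh
#' @param mesh a `tet_mesh`.
#' @param state a `solution_state` (or displacement vector); `NULL` for the
#'   reference configuration.
#' @param region optional region label to restrict to.
#' @return total (deformed) volume.
#' @export
deformed_volume <- function(mesh, state = NULL, region = NULL) {
  m2 <- mesh
  if (!is.null(state)) {
    u <- as_u_vector(state, nrow(mesh$nodes))
    m2$nodes <- mesh$nodes + matrix(u, ncol = 3L, byrow = TRUE)
  }
  v <- tet_volumes(m2)
  if (!is.null(region)) v <- v[mesh$region == region]
  sum(v)
}

#' Per-cell Cauchy stress magnitudes
#'
#' Frobenius norm of the Cauchy stress \eqn{\sigma = J^{-1} P_e F_e^T} in each
#' cell at the given state.
#' @inheritParams assemble_residual
#' @return numeric vector, one value per cell.
#' @export
cauchy_stress_norms <- function(mesh, state, materials, g = 1,
                                growth_region = "epithelium") {
  n <- nrow(mesh$nodes)
  u <- as_u_vector(state, n)
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  gc <- cell_growth_vector(mesh, g, growth_region)
  out <- numeric(nrow(mesh$cells))
  for (c in seq_len(nrow(mesh$cells))) {
    id <- mesh$cells[c, ]
    D <- t(mesh$nodes[id[2:4], , drop = FALSE]) -
      matrix(mesh$nodes[id[1], ], 3, 3)
    Di <- solve(D)
    G <- rbind(-colSums(Di), Di)
    F <- diag(3) + t(U[id, , drop = FALSE]) %*% G
    mat <- materials[[mesh$region[c]]]
    Fe <- F / gc[c]
    P <- first_pk_stress(Fe, mat)
    sig <- P %*% t(Fe) / det(Fe)
    out[c] <- sqrt(sum(sig^2))
  }
  out
}

#' Run a named simulation scenario on a mesh
#'
#' @description
#' Executes one of the study presets on a shell-in-lattice mesh and computes
#' the morphometric report:
#' * `pressure_only` — no growth, luminal pressure ramped to the target
#'   (inflation pushes the epithelium through the lattice holes);
#' * `growth_only` — epithelial growth ramped to the target, no pressure;
#' * `combined` — both ramped together.
#'
#' @param mesh a `tet_mesh` with a muscle lattice.
#' @param config a `run_config` (see [default_run_config()]); its `scenario`
#'   field is overridden by `scenario` if given.
#' @param scenario optional scenario name.
#' @param verbose print per-increment convergence lines.
#' @return list with `state` (a `solution_state`), `report` (a
#'   `morphometry_report`), `config`, and `scenario`.
#' @export
run_scenario <- function(mesh, config = default_run_config(),
                         scenario = NULL, verbose = FALSE) {
  if (!is.null(scenario)) config$scenario <- scenario
  sc <- match.arg(config$scenario,
                  c("pressure_only", "growth_only", "combined"))
  prog <- do.call(load_program, config$program)
  if (sc == "pressure_only") prog$g_target <- 1
  if (sc == "growth_only") prog$p_target <- 0
  prog$inflation_magnitude <- -prog$p_target
  materials <- lapply(config$materials,
                      function(m) material_region(m$E, m$nu))
  settings <- do.call(solver_settings, config$settings)
  st <- newton_solve(mesh, materials, prog, settings, verbose = verbose)
  rep <- morphometry_report(mesh, st)
  out <- list(state = st, report = rep, config = config, scenario = sc)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_outputs(mesh, st, rep, config)
  }
  out
}
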