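#' Deformed luminal surface points of a mesh
#' @param mesh a `tet_mesh`.
#' @param state optional `solution_state` or displacement vector; `NULL`
#'   gives the reference surface.
#' @return k x 3 matrix of (deformed) positions of the luminal surface nodes.
#' @export
luminal_points <- function(mesh, state = NULL) {
  ids <- sort(unique(as.vector(mesh$facets$luminal)))
  X <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(state)) {
    u <- as_u_vector(state, nrow(mesh$nodes))
    X <- X + matrix(u, ncol = 3L, byrow = TRUE)[ids, , drop = FALSE]
  }
  X
}

#' Aspect ratio of a surface point cloud
#'
#' @description
#' Length along the principal (proximal--distal) axis divided by the maximal
#' width perpendicular to it at the mid-section — the computational analogue
#' of measuring bronchus length and mid-bronchus width on a micrograph and
#' dividing the two.
#'
#' @param points k x 3 matrix of surface points (e.g. [luminal_points()]).
#' @param axis optional unit axis; by default the first principal component
#'   of `points`. Passing the reference-configuration axis keeps trajectories
#'   over a loading ramp comparable.
#' @param slab_fraction fraction of the length around the mid-point used as
#'   the "mid-section" when measuring the width (default 0.2).
#' @return scalar aspect ratio (length / width).
#' @export
aspect_ratio <- function(points, axis = NULL, slab_fraction = 0.2) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  if (nrow(points) < 4L) stop("degenerate surface: too few points")
  ctr <- colMeans(points)
  Xc <- sweep(points, 2, ctr)
  if (is.null(axis)) {
    axis <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.numeric(Xc %*% axis)
  len <- diff(range(proj))
  if (len <= 0) stop("degenerate surface: zero extent along principal axis")
  mid <- (max(proj) + min(proj)) / 2
  slab <- abs(proj - mid) <= slab_fraction * len / 2
  if (!any(slab)) stop("degenerate surface: empty mid-section slab")
  perp <- Xc[slab, , drop = FALSE] -
    outer(proj[slab], axis)
  width <- 2 * max(sqrt(rowSums(perp^2)))
  if (width <= 0) stop("degenerate surface: zero width")
  len / width
}

face_centroids <- function(nodes, faces) {
  (nodes[faces[, 1], , drop = FALSE] + nodes[faces[, 2], , drop = FALSE] +
     nodes[faces[, 3], , drop = FALSE]) / 3
}

face_normals <- function(nodes, faces) {
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm / sqrt(rowSums(nrm^2))
}

#' Epithelial thickness by normal ray casting
#'
#' @description
#' From the centroid of every luminal facet, a ray is cast along the facet's
#' inward normal (into the tissue) and the distance to the first intersection
#' with the deformed outer epithelial surface is the local wall thickness —
#' the same reading a thickness measurement on a 2D optical section gives.
#' Rays that miss the outer surface (severely folded configurations) are
#' flagged and excluded from the summary.
#'
#' @param mesh a `tet_mesh`.
#' @param state optional `solution_state` or displacement; `NULL` measures the
#'   reference configuration.
#' @param max_factor rays longer than `max_factor` times the mesh diameter are
#'   treated as misses.
#' @param method `"ray"` (default; matches reading thickness off an optical
#'   section) or `"nearest"` (distance to the closest point of the outer
#'   surface, a lower bound that never misses).
#' @return list with `thickness` (per luminal facet, `NA` for misses),
#'   `mean`, `sd`, `n_missed`.
#' @export
epithelial_thickness <- function(mesh, state = NULL, max_factor = 0.5,
                                 method = c("ray", "nearest")) {
  method <- match.arg(method)
  n <- nrow(mesh$nodes)
  nodes <- mesh$nodes
  if (!is.null(state)) {
    u <- as_u_vector(state, n)
    nodes <- nodes + matrix(u, ncol = 3L, byrow = TRUE)
  }
  lum <- mesh$facets$luminal
  orig <- face_centroids(nodes, lum)
  # luminal facets are wound outward w.r.t. the solid (into the lumen);
  # the inward tissue normal is the negative
  dirs <- -face_normals(nodes, lum)
  os <- epithelial_outer_surface(mesh)
  if (method == "nearest") {
    th <- nearest_tri_distance(orig,
                               nodes[os$faces[, 1], , drop = FALSE],
                               nodes[os$faces[, 2], , drop = FALSE],
                               nodes[os$faces[, 3], , drop = FALSE])
  } else {
    tmax <- max_factor * sqrt(sum((apply(nodes, 2, max) -
                                     apply(nodes, 2, min))^2))
    th <- ray_cast_first_hit(orig, dirs,
                             nodes[os$faces[, 1], , drop = FALSE],
                             nodes[os$faces[, 2], , drop = FALSE],
                             nodes[os$faces[, 3], , drop = FALSE],
                             1e-10, tmax)
  }
  ok <- !is.na(th)
  list(thickness = th, mean = mean(th[ok]), sd = stats::sd(th[ok]),
       n_missed = sum(!ok))
}

#' Per-hole protrusion amplitudes
#'
#' @description
#' For every open hole of the muscle lattice (enumerated by [hole_patches()]
#' in the reference configuration), the maximum outward-normal displacement of
#' the epithelial outer surface within the hole, minus the mean outward
#' displacement of the band-covered surface adjacent to that hole. Positive
#' values mean the epithelium protrudes through the hole relative to the
#' surrounding bands.
#'
#' @param mesh a `tet_mesh`.
#' @param state a `solution_state` or displacement vector.
#' @return data frame with one row per hole: `hole`, `amplitude`,
#'   `max_outward`, `band_reference`, `n_faces`.
#' @export
protrusion_amplitudes <- function(mesh, state) {
  hp <- hole_patches(mesh)
  if (hp$n_holes == 0L) {
    warning("mesh has no lattice holes (full muscle coverage)")
    return(data.frame(hole = integer(0), amplitude = numeric(0),
                      max_outward = numeric(0), band_reference = numeric(0),
                      n_faces = integer(0)))
  }
  n <- nrow(mesh$nodes)
  u <- as_u_vector(state, n)
  Udisp <- matrix(u, ncol = 3L, byrow = TRUE)
  os <- epithelial_outer_surface(mesh)
  cov_faces <- os$faces[os$covered, , drop = FALSE]

  # displacements are taken relative to the mean displacement of the outer
  # epithelial surface, so a rigid translation of the solution (a pure gauge
  # change) leaves every amplitude untouched
  surf_nodes <- unique(as.vector(os$faces))
  u_mean <- colMeans(Udisp[surf_nodes, , drop = FALSE])
  out_disp <- function(faces) {
    Nref <- face_normals(mesh$nodes, faces)  # outward in reference
    dc <- sweep(face_centroids(Udisp, faces), 2, u_mean)
    rowSums(dc * Nref)
  }
  hole_disp <- out_disp(hp$faces)
  cov_disp <- if (nrow(cov_faces)) out_disp(cov_faces) else numeric(0)

  res <- lapply(seq_len(hp$n_holes), function(h) {
    idx <- hp$patch == h
    patch_nodes <- unique(as.vector(hp$faces[idx, , drop = FALSE]))
    adj <- if (nrow(cov_faces))
      which(rowSums(matrix(cov_faces %in% patch_nodes, ncol = 3L)) > 0)
    else integer(0)
    band_ref <- if (length(adj)) mean(cov_disp[adj]) else 0
    mx <- max(hole_disp[idx])
    data.frame(hole = h, amplitude = mx - band_ref, max_outward = mx,
               band_reference = band_ref, n_faces = sum(idx))
  })
  do.call(rbind, res)
}

#' Morphometric report for a simulated state
#'
#' @description
#' Bundles the study's comparative measurements: aspect ratio of the deformed
#' luminal surface (principal axis fixed from the reference configuration),
#' epithelial thickness statistics before and after deformation, the thinning
#' ratio (mean final / mean initial thickness; 1 for no deformation, < 1 for
#' wall thinning), and per-hole protrusion amplitudes.
#'
#' @param mesh a `tet_mesh`.
#' @param state a `solution_state` (or displacement vector).
#' @return object of class `morphometry_report`.
#' @export
morphometry_report <- function(mesh, state) {
  ref_pts <- luminal_points(mesh)
  ctr <- colMeans(ref_pts)
  ax <- svd(sweep(ref_pts, 2, ctr), nu = 0, nv = 1)$v[, 1]
  th0 <- epithelial_thickness(mesh)
  th1 <- epithelial_thickness(mesh, state)
  pro <- if (hole_patches(mesh)$n_holes > 0)
    protrusion_amplitudes(mesh, state)
  else data.frame(hole = integer(0), amplitude = numeric(0),
                  max_outward = numeric(0), band_reference = numeric(0),
                  n_faces = integer(0))
  structure(list(
    aspect_ratio = aspect_ratio(luminal_points(mesh, state), axis = ax),
    aspect_ratio_reference = aspect_ratio(ref_pts, axis = ax),
    thickness_initial = th0, thickness_final = th1,
    thinning_ratio = th1$mean / th0$mean,
    protrusions = pro), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  cat(sprintf("  aspect ratio:       %.3f (reference %.3f)\n",
              x$aspect_ratio, x$aspect_ratio_reference))
  cat(sprintf("  thickness initial:  %.4f +/- %.4f\n",
              x$thickness_initial$mean, x$thickness_initial$sd))
  cat(sprintf("  thickness final:    %.4f +/- %.4f (%d rays missed)\n",
              x$thickness_final$mean, x$thickness_final$sd,
              x$thickness_final$n_missed))
  cat(sprintf("  thinning ratio:     %.4f\n", x$thinning_ratio))
  if (nrow(x$protrusions))
    cat(sprintf("  protrusion (n=%d):  min %.4f, mean %.4f, max %.4f\n",
                nrow(x$protrusions), min(x$protrusions$amplitude),
                mean(x$protrusions$amplitude), max(x$protrusions$amplitude)))
  invisible(x)
}

#' Thinning ratios of two scenarios at matched mean protrusion
#'
#' @description
#' Reads the per-increment ramp trajectories of two solved scenarios, finds
#' the largest mean protrusion amplitude both reach, and linearly interpolates
#' each scenario's thinning ratio at that common protrusion level. This makes
#' thinning comparable between a pressure-driven and a growth-driven run even
#' when their final deformations differ.
#'
#' @param mesh a `tet_mesh` (shared by both runs).
#' @param state_a,state_b `solution_state`s with stored increments.
#' @return list with `match_level` (the common mean protrusion) and
#'   `thinning_a`, `thinning_b` interpolated at that level, plus the raw
#'   trajectories.
#' @export
matched_protrusion_thinning <- function(mesh, state_a, state_b) {
  traj <- function(st) {
    t(vapply(st$increments, function(inc) {
      pro <- protrusion_amplitudes(mesh, inc$u)
      th <- epithelial_thickness(mesh, inc$u)
      c(protrusion = mean(pro$amplitude), thickness = th$mean)
    }, c(protrusion = 0, thickness = 0)))
  }
  th0 <- epithelial_thickness(mesh)$mean
  ta <- traj(state_a); tb <- traj(state_b)
  ta <- rbind(c(0, th0), ta); tb <- rbind(c(0, th0), tb)
  match_level <- min(max(ta[, 1]), max(tb[, 1]))
  if (match_level <= 0)
    stop("scenarios show no common positive protrusion level to match")
  interp <- function(tr) {
    stats::approx(tr[, 1], tr[, 2], xout = match_level, ties = "ordered")$y
  }
  list(match_level = match_level,
       thinning_a = interp(ta) / th0,
       thinning_b = interp(tb) / th0,
       trajectory_a = ta, trajectory_b = tb)
}
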