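#' Geometry parameters for the shell-in-lattice model
#'
#' @description
#' Parametric description of the synthetic anatomy: a closed capsule-shaped
#' epithelial shell (cylindrical body with hemispherical caps) whose outer
#' surface carries a bonded lattice of stiffer smooth-muscle bands —
#' circumferential rings plus longitudinal (meridian) bands — leaving open
#' rectangular holes. All lengths are in units of the shell radius.
#'
#' The muscle lattice always includes a polar cap of muscle at each end of the
#' capsule (the closed ends of the string-bag-like mesh), `n_rings` interior
#' circumferential rings, and `n_longitudinal` meridian bands running cap to
#' cap, so the number of open holes is `(n_rings + 1) * n_longitudinal`.
#'
#' @param shell_length total tip-to-tip length of the capsule (>= 2 *
#'   `shell_radius`; equality gives a sphere).
#' @param shell_radius outer radius of the epithelial shell; the length unit
#'   (default 1).
#' @param shell_thickness epithelial wall thickness, in `(0, shell_radius)`.
#' @param n_rings number of interior circumferential muscle rings (>= 0).
#' @param n_longitudinal number of longitudinal muscle bands (>= 0).
#' @param band_width width of the muscle bands (arc length); band placement is
#'   snapped to the structured surface grid, so the realized width is the
#'   nearest whole number of grid cells (at least one).
#' @param band_thickness radial thickness of the muscle layer.
#' @param target_edge_length requested mesh edge length; must resolve the
#'   bands (`target_edge_length < band_width` when a lattice is present).
#' @param n_radial_layers element layers through the epithelial wall
#'   (default: whatever `target_edge_length` implies, at least 1).
#' @param seed integer recorded with the mesh and used when `jitter > 0`.
#' @param jitter relative azimuthal node jitter amplitude (default 0, i.e.
#'   a perfectly regular grid).
#' @return Object of class `geometry_params`.
#' @examples
#' geometry_params()                       # study defaults, 48 holes
#' geometry_params(n_rings = 0, n_longitudinal = 0)  # bare shell
#' @export
geometry_params <- function(shell_length = 4,
                            shell_radius = 1,
                            shell_thickness = 0.3,
                            n_rings = 5,
                            n_longitudinal = 8,
                            band_width = 0.25,
                            band_thickness = 0.15,
                            target_edge_length = 0.2,
                            n_radial_layers = NULL,
                            seed = 1L,
                            jitter = 0) {
  if (shell_radius <= 0) stop("shell_radius must be positive")
  if (shell_thickness <= 0 || shell_thickness >= shell_radius)
    stop("shell_thickness must lie strictly between 0 and shell_radius, got ",
         shell_thickness)
  if (shell_length < 2 * shell_radius)
    stop("shell_length must be at least the capsule diameter 2*shell_radius")
  if (n_rings < 0 || n_longitudinal < 0)
    stop("band counts must be non-negative")
  lattice <- n_rings > 0 || n_longitudinal > 0
  if (lattice) {
    if (band_width <= 0 || band_thickness <= 0)
      stop("band_width and band_thickness must be positive")
    if (target_edge_length >= band_width)
      stop("target_edge_length (", target_edge_length, ") must be smaller ",
           "than band_width (", band_width, ") so the mesh resolves the ",
           "muscle struts")
  }
  if (target_edge_length <= 0) stop("target_edge_length must be positive")
  if (is.null(n_radial_layers))
    n_radial_layers <- max(1L, round(shell_thickness / target_edge_length))
  structure(list(shell_length = shell_length, shell_radius = shell_radius,
                 shell_thickness = shell_thickness, n_rings = as.integer(n_rings),
                 n_longitudinal = as.integer(n_longitudinal),
                 band_width = band_width, band_thickness = band_thickness,
                 target_edge_length = target_edge_length,
                 n_radial_layers = as.integer(n_radial_layers),
                 seed = as.integer(seed), jitter = jitter),
            class = "geometry_params")
}

#' Expected number of lattice holes for a parameter set
#'
#' The construction (polar caps + `n_rings` rings + `n_longitudinal` meridian
#' bands) leaves `(n_rings + 1) * max(n_longitudinal, 1)` open holes when a
#' lattice is present, and none otherwise.
#' @param params a [geometry_params()].
#' @return integer hole count.
#' @export
expected_hole_count <- function(params) {
  if (params$n_rings == 0 && params$n_longitudinal == 0) return(0L)
  (params$n_rings + 1L) * max(params$n_longitudinal, 1L)
}

#' Analytic volume of the capsule shell wall
#'
#' Constructive-geometry reference volume of the epithelial wall: a spherical
#' shell plus a cylindrical tube,
#' \eqn{V = \frac{4\pi}{3}(R^3 - R_i^3) + \pi (R^2 - R_i^2) L_c}
#' with \eqn{R_i = R - h} and cylinder length \eqn{L_c = L - 2R}.
#' @param params a [geometry_params()].
#' @return scalar volume.
#' @export
capsule_shell_volume <- function(params) {
  R <- params$shell_radius
  Ri <- R - params$shell_thickness
  Lc <- params$shell_length - 2 * R
  4 * pi / 3 * (R^3 - Ri^3) + pi * (R^2 - Ri^2) * Lc
}

# profile of the capsule offset surface: arc-length parameter t in [0, T],
# offset s from the outer surface (s < 0 inward). Returns cbind(rho, z).
capsule_profile <- function(t, s, R, Lc) {
  qa <- pi * R / 2
  rho <- numeric(length(t)); z <- numeric(length(t))
  capA <- t <= qa + 1e-12
  cyl  <- !capA & t < qa + Lc - 1e-12
  capB <- !capA & !cyl
  phi <- t[capA] / R
  rho[capA] <- (R + s) * sin(phi)
  z[capA] <- -Lc / 2 - (R + s) * cos(phi)
  rho[cyl] <- R + s
  z[cyl] <- -Lc / 2 + (t[cyl] - qa)
  Ttot <- pi * R + Lc
  phiB <- (Ttot - t[capB]) / R
  rho[capB] <- (R + s) * sin(phiB)
  z[capB] <- Lc / 2 + (R + s) * cos(phiB)
  cbind(rho = pmax(rho, 0), z = z)
}

# split a quad cycle (a,b,c,d) into two triangles along the diagonal through
# its smallest global node index (keeps shared faces conforming).
split_quad <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (which.min(v) %in% c(1L, 3L)) {
    rbind(c(a, b, c), c(a, c, d))
  } else {
    rbind(c(b, c, d), c(b, d, a))
  }
}

# consistent 3-tet decomposition of a prism (p[1:3] bottom, p[4:6] top):
# rotate the smallest index to position 1, then pick the free quad diagonal
# by the same smallest-index rule, so neighbouring prisms always agree.
prism_perms <- list(c(1L,2L,3L,4L,5L,6L), c(2L,3L,1L,5L,6L,4L),
                    c(3L,1L,2L,6L,4L,5L), c(4L,6L,5L,1L,3L,2L),
                    c(5L,4L,6L,2L,1L,3L), c(6L,5L,4L,3L,2L,1L))

split_prism <- function(p) {
  q <- p[prism_perms[[which.min(p)]]]
  if (min(q[2], q[6]) < min(q[3], q[5])) {
    rbind(c(q[1], q[2], q[3], q[6]),
          c(q[1], q[2], q[6], q[5]),
          c(q[1], q[5], q[6], q[4]))
  } else {
    rbind(c(q[1], q[2], q[3], q[5]),
          c(q[1], q[5], q[3], q[6]),
          c(q[1], q[5], q[6], q[4]))
  }
}

# signed volumes of all tetrahedra
#' Signed reference volumes of all cells
#' @param mesh a `tet_mesh`.
#' @return numeric vector, one signed volume per tetrahedron.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; cl <- mesh$cells
  a <- nd[cl[, 1], , drop = FALSE]
  d1 <- nd[cl[, 2], , drop = FALSE] - a
  d2 <- nd[cl[, 3], , drop = FALSE] - a
  d3 <- nd[cl[, 4], , drop = FALSE] - a
  (d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
   d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
   d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])) / 6
}

# all 4 faces of each tet, wound outward for a positively oriented tet
tet_faces_outward <- function(cells) {
  rbind(cells[, c(1, 3, 2), drop = FALSE],
        cells[, c(1, 2, 4), drop = FALSE],
        cells[, c(2, 3, 4), drop = FALSE],
        cells[, c(1, 4, 3), drop = FALSE])
}

face_key <- function(f) {
  s <- t(apply(f, 1, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

# boundary faces (appearing once), outward-wound, with owner cell index
boundary_faces_of <- function(cells, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(cells))
  cl <- cells[subset, , drop = FALSE]
  faces <- tet_faces_outward(cl)
  owner <- rep(subset, 4L)
  key <- face_key(faces)
  tab <- table(key)
  once <- names(tab)[tab == 1L]
  keep <- key %in% once
  list(faces = faces[keep, , drop = FALSE], owner = owner[keep])
}

#' Generate the shell-in-lattice tetrahedral mesh
#'
#' @description
#' Builds the synthetic study geometry: a closed capsule epithelial shell
#' meshed with first-order tetrahedra, with a conforming bonded muscle lattice
#' (shared interface nodes, no contact) on its outer surface. The structured
#' generator triangulates a latitude–longitude surface grid, extrudes it
#' radially into prisms, and splits each prism into three tetrahedra with a
#' globally consistent diagonal rule, so the mesh is conforming everywhere.
#'
#' @param params a [geometry_params()].
#' @return Object of class `tet_mesh` with fields
#'   `nodes` (n x 3 reference coordinates), `cells` (m x 4 node indices,
#'   positively oriented), `region` (character per cell, `"epithelium"` or
#'   `"muscle"`), `facets` (list of oriented boundary triangles: `luminal`,
#'   `external`), and `meta` (generation parameters and grid sizes).
#' @examples
#' m <- make_shell_in_lattice(geometry_params(target_edge_length = 0.35,
#'                                            band_width = 0.4))
#' table(m$region)
#' @export
make_shell_in_lattice <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  R <- params$shell_radius
  h <- params$shell_thickness
  Lc <- params$shell_length - 2 * R
  Ttot <- pi * R + Lc
  edge <- params$target_edge_length
  lattice <- params$n_rings > 0 || params$n_longitudinal > 0

  nth <- max(8L, round(2 * pi * R / edge))
  if (lattice && params$n_longitudinal > 0) {
    m <- max(2L, round(2 * pi * R / (edge * params$n_longitudinal)))
    nth <- params$n_longitudinal * m
  }
  nt <- max(4L, round(Ttot / edge))
  if (nt %% 2L == 1L) nt <- nt + 1L
  nr <- params$n_radial_layers
  nrb <- if (lattice) max(1L, round(params$band_thickness / edge)) else 0L

  dth <- 2 * pi / nth
  dt <- Ttot / nt
  tvals <- seq(0, Ttot, length.out = nt + 1)

  # --- band classification on the (row, column) cell grid -------------------
  row_cov <- rep(FALSE, nt)  # cells it = 1..nt
  col_cov <- rep(FALSE, nth)
  if (lattice) {
    ncap <- max(1L, round(params$band_width / dt))
    row_cov[seq_len(ncap)] <- TRUE
    row_cov[nt - seq_len(ncap) + 1L] <- TRUE
    if (params$n_rings > 0) {
      rrows <- max(1L, round(params$band_width / dt))
      cap_t <- ncap * dt
      span <- Ttot - 2 * cap_t
      for (i in seq_len(params$n_rings)) {
        tc <- cap_t + span * i / (params$n_rings + 1)
        ric <- max(1L, min(nt, round(tc / dt + 0.5)))
        lo <- ric - (rrows - 1L) %/% 2L
        hi <- ric + rrows %/% 2L
        row_cov[max(1L, lo):min(nt, hi)] <- TRUE
      }
    }
    if (params$n_longitudinal > 0) {
      bcols <- max(1L, round(params$band_width / (R * dth)))
      for (k in seq_len(params$n_longitudinal) - 1L) {
        jc <- round(k * nth / params$n_longitudinal + 0.5)
        cols <- (jc - (bcols - 1L) %/% 2L):(jc + bcols %/% 2L)
        col_cov[(cols - 1L) %% nth + 1L] <- TRUE
      }
    }
    # gap sanity: number of uncovered runs must match the analytic hole grid
    runs_rows <- sum(diff(c(TRUE, row_cov)) == -1L)
    if (runs_rows != params$n_rings + 1L)
      stop("infeasible lattice: rings overlap or leave no gaps (",
           runs_rows, " gap rows, expected ", params$n_rings + 1L,
           "); reduce band_width or n_rings")
    if (params$n_longitudinal > 0) {
      cc <- col_cov
      runs_cols <- sum(diff(c(cc[nth], cc)) == -1L)
      if (runs_cols != params$n_longitudinal)
        stop("infeasible lattice: longitudinal bands overlap or leave no ",
             "gaps (", runs_cols, " gap columns, expected ",
             params$n_longitudinal, "); reduce band_width or n_longitudinal")
    }
  }
  cell_cov <- outer(row_cov, col_cov, function(a, b) a | b)  # nt x nth

  # --- node grid ------------------------------------------------------------
  nlay <- nr + nrb                       # element layers; node layers 0..nlay
  M <- (nt - 1L) * nth + 2L              # nodes per layer
  nid <- function(it, j, l) {
    # it in 0..nt (0 and nt are poles), j in 0..nth-1 (wrapped), layer l
    len <- max(length(it), length(j), length(l))
    it <- rep_len(it, len); j <- rep_len(j, len) %% nth
    base <- rep_len(l, len) * M
    out <- base + 1L + (it - 1L) * nth + j + 1L
    out[it == 0L] <- base[it == 0L] + 1L
    out[it == nt] <- base[it == nt] + M
    as.integer(out)
  }
  svals <- c(seq(-h, 0, length.out = nr + 1),
             if (nrb > 0) params$band_thickness * seq_len(nrb) / nrb)

  theta <- (seq_len(nth) - 1L) * dth
  if (params$jitter > 0) {
    set.seed(params$seed)
    jit <- matrix(stats::runif((nt - 1L) * nth, -0.5, 0.5) * dth *
                    params$jitter, nt - 1L, nth)
  }
  coords <- matrix(NA_real_, (nlay + 1L) * M, 3L)
  for (l in 0:nlay) {
    s <- svals[l + 1L]
    pr <- capsule_profile(tvals, s, R, Lc)
    coords[nid(0L, 0L, l), ] <- c(0, 0, pr[1L, "z"])
    coords[nid(nt, 0L, l), ] <- c(0, 0, pr[nt + 1L, "z"])
    for (it in 1:(nt - 1L)) {
      th <- theta
      if (params$jitter > 0) th <- th + jit[it, ]
      ids <- nid(it, 0:(nth - 1L), l)
      coords[ids, 1L] <- pr[it + 1L, "rho"] * cos(th)
      coords[ids, 2L] <- pr[it + 1L, "rho"] * sin(th)
      coords[ids, 3L] <- pr[it + 1L, "z"]
    }
  }

  # --- surface triangulation (per cell row it = 1..nt, column j) ------------
  tris <- vector("list", nt * nth)
  tri_row <- integer(0); tri_col <- integer(0)
  cnt <- 0L
  for (it in 1:nt) {
    for (j in 0:(nth - 1L)) {
      cnt <- cnt + 1L
      if (it == 1L) {
        tr <- rbind(c(nid(0L, 0L, 0L), nid(1L, j, 0L), nid(1L, j + 1L, 0L)))
      } else if (it == nt) {
        tr <- rbind(c(nid(nt - 1L, j, 0L), nid(nt, 0L, 0L),
                      nid(nt - 1L, j + 1L, 0L)))
      } else {
        tr <- split_quad(nid(it - 1L, j, 0L), nid(it, j, 0L),
                         nid(it, j + 1L, 0L), nid(it - 1L, j + 1L, 0L))
      }
      tris[[cnt]] <- tr
      tri_row <- c(tri_row, rep(it, nrow(tr)))
      tri_col <- c(tri_col, rep(j + 1L, nrow(tr)))
    }
  }
  surf <- do.call(rbind, tris)            # node ids at layer 0

  # --- extrusion into prisms and tetrahedra ---------------------------------
  cells_list <- list(); region_list <- list()
  lay_of <- function(ids, l) ids + l * M  # layer shift (ids are layer-0 ids)
  for (l in 0:(nlay - 1L)) {
    muscle <- l >= nr
    if (muscle) {
      keep <- cell_cov[cbind(tri_row, tri_col)]
      st <- surf[keep, , drop = FALSE]
    } else st <- surf
    if (nrow(st) == 0L) next
    tets <- matrix(0L, 3L * nrow(st), 4L)
    for (k in seq_len(nrow(st))) {
      p <- c(lay_of(st[k, ], l), lay_of(st[k, ], l + 1L))
      tets[(3L * k - 2L):(3L * k), ] <- split_prism(p)
    }
    cells_list[[length(cells_list) + 1L]] <- tets
    region_list[[length(region_list) + 1L]] <-
      rep(if (muscle) "muscle" else "epithelium", nrow(tets))
  }
  cells <- do.call(rbind, cells_list)
  region <- unlist(region_list)

  # --- drop unused nodes, remap, orient -------------------------------------
  used <- sort(unique(as.vector(cells)))
  remap <- integer(nrow(coords)); remap[used] <- seq_along(used)
  cells <- matrix(remap[cells], ncol = 4L)
  nodes <- coords[used, , drop = FALSE]
  lum_nodes <- remap[intersect(used, 1:M)]   # layer-0 nodes (luminal surface)

  mesh <- structure(list(nodes = nodes, cells = cells, region = region,
                         facets = NULL,
                         meta = list(params = params, nt = nt, nth = nth,
                                     nr = nr, nrb = nrb, Ttot = Ttot)),
                    class = "tet_mesh")
  vol <- tet_volumes(mesh)
  neg <- which(vol < 0)
  if (length(neg)) {
    mesh$cells[neg, 3:4] <- mesh$cells[neg, 4:3]
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0))
    stop("mesher produced degenerate (zero-volume) elements; ",
         "refine target_edge_length")

  bf <- boundary_faces_of(mesh$cells)
  on_lum <- matrix(bf$faces %in% lum_nodes, ncol = 3L)
  is_lum <- rowSums(on_lum) == 3L
  mesh$facets <- list(luminal = bf$faces[is_lum, , drop = FALSE],
                      external = bf$faces[!is_lum, , drop = FALSE])
  mesh$meta$luminal_owner <- bf$owner[is_lum]
  mesh$meta$external_owner <- bf$owner[!is_lum]
  mesh
}

#' Generate a closed spherical shell benchmark mesh
#'
#' Thick-walled sphere used by the verification benchmarks; all cells are
#' epithelium-labeled, the inner boundary is the `luminal` facet set and the
#' outer boundary the `external` set.
#'
#' @param inner_radius,outer_radius shell radii, `0 < inner < outer`.
#' @param target_edge_length mesh resolution.
#' @param n_radial_layers optional number of element layers through the wall.
#' @return a `tet_mesh`.
#' @examples
#' s <- make_sphere_shell(0.8, 1, 0.35)
#' sum(tet_volumes(s))           # close to 4*pi/3*(1 - 0.8^3)
#' @export
make_sphere_shell <- function(inner_radius, outer_radius, target_edge_length,
                              n_radial_layers = NULL) {
  if (!(inner_radius > 0) || inner_radius >= outer_radius)
    stop("need 0 < inner_radius < outer_radius, got ",
         inner_radius, " and ", outer_radius)
  p <- geometry_params(shell_length = 2 * outer_radius,
                       shell_radius = outer_radius,
                       shell_thickness = outer_radius - inner_radius,
                       n_rings = 0L, n_longitudinal = 0L,
                       band_width = Inf, band_thickness = 1,
                       target_edge_length = target_edge_length,
                       n_radial_layers = n_radial_layers)
  make_shell_in_lattice(p)
}

#' Validate a tetrahedral mesh
#'
#' @description
#' Checks the structural invariants of a `tet_mesh` and returns a character
#' vector of human-readable violations (empty if the mesh is valid):
#' positive cell volumes, boundary facet sets that are disjoint and jointly
#' cover the boundary, luminal facets owned by epithelium cells, no duplicated
#' (non-conforming) nodes, and edge-connectivity of each region.
#'
#' @param mesh a `tet_mesh`.
#' @return character vector of diagnostics; `character(0)` for a valid mesh.
#' @export
validate_mesh <- function(mesh) {
  diags <- character(0)
  vol <- tet_volumes(mesh)
  bad <- which(vol <= 0)
  if (length(bad))
    diags <- c(diags, paste0("negative or zero reference volume in cell(s) ",
                             paste(utils::head(bad, 5L), collapse = ", "),
                             if (length(bad) > 5L) " ..."))

  bf <- boundary_faces_of(mesh$cells)
  bkey <- face_key(bf$faces)
  lkey <- face_key(mesh$facets$luminal)
  ekey <- face_key(mesh$facets$external)
  if (length(intersect(lkey, ekey)))
    diags <- c(diags, "facet sets 'luminal' and 'external' are not disjoint")
  if (!setequal(c(lkey, ekey), bkey))
    diags <- c(diags, paste0("facet sets do not cover the mesh boundary ",
                             "exactly (", length(bkey), " boundary faces vs ",
                             length(lkey) + length(ekey), " tagged)"))

  # luminal facets must belong to epithelium cells
  own <- bf$owner[match(lkey, bkey)]
  own <- own[!is.na(own)]
  if (length(own) && any(mesh$region[own] != "epithelium"))
    diags <- c(diags, paste0("luminal facet(s) owned by non-epithelium ",
                             "cell(s): ",
                             paste(utils::head(own[mesh$region[own] !=
                                                     "epithelium"], 5L),
                                   collapse = ", ")))

  # conformity: no two distinct nodes at (numerically) the same location
  key <- paste(round(mesh$nodes[, 1], 9), round(mesh$nodes[, 2], 9),
               round(mesh$nodes[, 3], 9))
  if (anyDuplicated(key))
    diags <- c(diags, "duplicated node coordinates (non-conforming interface)")

  # region edge-connectivity
  for (reg in unique(mesh$region)) {
    idx <- which(mesh$region == reg)
    if (length(idx) < 2L) next
    if (!region_edge_connected(mesh$cells[idx, , drop = FALSE]))
      diags <- c(diags, paste0("region '", reg, "' is not edge-connected"))
  }
  diags
}

# are the given cells connected through shared edges?
region_edge_connected <- function(cells) {
  ne <- nrow(cells)
  ep <- rbind(cells[, c(1, 2)], cells[, c(1, 3)], cells[, c(1, 4)],
              cells[, c(2, 3)], cells[, c(2, 4)], cells[, c(3, 4)])
  key <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
  cellid <- rep(seq_len(ne), 6L)
  groups <- split(cellid, key)
  # union-find over cells
  parent <- seq_len(ne)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in groups) {
    if (length(g) < 2L) next
    r <- find(g[1L])
    for (x in g[-1L]) { rx <- find(x); if (rx != r) parent[rx] <- r }
  }
  length(unique(vapply(seq_len(ne), find, 1L))) == 1L
}

#' Outer surface of the epithelium region
#'
#' All faces bounding the epithelium-labeled cells except the luminal ones —
#' i.e. the epithelium's outer surface, whether exposed (hole) or bonded to a
#' muscle band. Faces are wound outward (away from the epithelium).
#'
#' @param mesh a `tet_mesh`.
#' @return list with `faces` (k x 3), `owner` (owning epithelium cell), and
#'   `covered` (logical: bonded to muscle rather than exposed).
#' @export
epithelial_outer_surface <- function(mesh) {
  epi <- which(mesh$region == "epithelium")
  bf <- boundary_faces_of(mesh$cells, subset = epi)
  key <- face_key(bf$faces)
  lum <- face_key(mesh$facets$luminal)
  keep <- !(key %in% lum)
  faces <- bf$faces[keep, , drop = FALSE]
  ext <- face_key(mesh$facets$external)
  covered <- !(face_key(faces) %in% ext)
  list(faces = faces, owner = bf$owner[keep], covered = covered)
}

#' Enumerate lattice holes by flood fill
#'
#' Uncovered outer-surface facets of the epithelium are grouped into
#' edge-connected patches; each patch is one open hole of the muscle lattice.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `faces` (uncovered outer faces), `patch` (integer patch
#'   id per face), and `n_holes`.
#' @export
hole_patches <- function(mesh) {
  if (!any(mesh$region == "muscle")) {
    # no lattice, hence no holes (the whole outer surface is free)
    return(list(faces = matrix(integer(0), 0, 3), patch = integer(0),
                n_holes = 0L))
  }
  os <- epithelial_outer_surface(mesh)
  faces <- os$faces[!os$covered, , drop = FALSE]
  nf <- nrow(faces)
  if (nf == 0L)
    return(list(faces = faces, patch = integer(0), n_holes = 0L))
  ep <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
  fid <- rep(seq_len(nf), 3L)
  parent <- seq_len(nf)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in split(fid, key)) {
    if (length(g) < 2L) next
    r <- find(g[1L])
    for (x in g[-1L]) { rx <- find(x); if (rx != r) parent[rx] <- r }
  }
  root <- vapply(seq_len(nf), find, 1L)
  patch <- match(root, unique(root))
  list(faces = faces, patch = patch, n_holes = length(unique(patch)))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(paste0("<tet_mesh> %d nodes, %d tets (%d epithelium, ",
                     "%d muscle), %d luminal + %d external boundary faces\n"),
              nrow(x$nodes), nrow(x$cells), sum(x$region == "epithelium"),
              sum(x$region == "muscle"), nrow(x$facets$luminal),
              nrow(x$facets$external)))
  invisible(x)
}
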