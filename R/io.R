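#' Default run configuration
#'
#' @description
#' The resolved study defaults: epithelium `E = 1.0`, smooth muscle
#' `E = 10.0`, Poisson's ratio `0.3` for both, growth target `g = 2.0` in the
#' epithelium and signed luminal pressure `p = -0.2` (inflation magnitude
#' 0.2), ramped linearly over 20 increments on the default shell-in-lattice
#' geometry. The seed is recorded with every run even when no stochastic
#' component is active, so an archived configuration fully determines a rerun.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(shell_length = 4, shell_radius = 1,
                    shell_thickness = 0.3, n_rings = 5L,
                    n_longitudinal = 8L, band_width = 0.25,
                    band_thickness = 0.15, target_edge_length = 0.2,
                    seed = 1L, jitter = 0),
    materials = list(epithelium = list(E = 1.0, nu = 0.3),
                     muscle = list(E = 10.0, nu = 0.3)),
    program = list(g_target = 2.0, p_target = -0.2, n_increments = 20L,
                   growth_region = "epithelium"),
    settings = list(newton_rel_tol = 1e-8, newton_abs_tol = 1e-10,
                    max_newton_iter = 25L, max_halvings = 4L),
    scenario = "combined",
    output_dir = NULL,
    seed = 1L), class = "run_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- list(user[[key]])  # preserves explicit NULLs
    }
  }
  defaults
}

validate_config <- function(cfg) {
  for (reg in names(cfg$materials)) {
    m <- cfg$materials[[reg]]
    if (m$E <= 0)
      stop("materials.", reg, ".E must be positive, got ", m$E)
    if (m$nu <= -1 || m$nu >= 0.5)
      stop("materials.", reg, ".nu must lie in (-1, 0.5) (the compressible ",
           "model excludes nu = 0.5), got ", m$nu)
  }
  if (cfg$program$g_target <= 0)
    stop("program.g_target must be positive")
  if (cfg$program$n_increments < 1)
    stop("program.n_increments must be >= 1")
  if (!cfg$scenario %in% c("pressure_only", "growth_only", "combined"))
    stop("scenario must be one of pressure_only, growth_only, combined; ",
         "got '", cfg$scenario, "'")
  # geometry invariants checked by geometry_params()
  do.call(geometry_params, cfg$geometry)
  cfg
}

#' Load and validate a run configuration from YAML
#'
#' Missing keys are filled from [default_run_config()]; unknown keys are
#' rejected with the offending key named. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  cfg$program$inflation_magnitude <- NULL  # derived, not user-set
  structure(validate_config(cfg), class = "run_config")
}

#' Save a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the mesh described by a run configuration
#' @param config a `run_config`.
#' @return a `tet_mesh`.
#' @export
mesh_from_config <- function(config) {
  make_shell_in_lattice(do.call(geometry_params, config$geometry))
}

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Write a VTU snapshot of a (possibly deformed) state
#'
#' ASCII XML UnstructuredGrid with point field `displacement` and cell fields
#' `region`, `Je`, `psi`; loadable in standard visualization tools.
#'
#' @param mesh a `tet_mesh`.
#' @param state optional `solution_state` or displacement vector (`NULL`
#'   writes the reference configuration with zero displacement).
#' @param path output `.vtu` path.
#' @param Je,psi optional per-cell fields (taken from `state` when present).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, state = NULL, path, Je = NULL, psi = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells)
  u <- if (is.null(state)) numeric(3 * n) else as_u_vector(state, n)
  if (is.null(Je) && is.list(state) && !is.null(state$Je)) Je <- state$Je
  if (is.null(psi) && is.list(state) && !is.null(state$psi)) psi <- state$psi
  if (is.null(Je)) Je <- rep(1, m)
  if (is.null(psi)) psi <- rep(0, m)
  reg <- as.integer(factor(mesh$region, levels = c("epithelium", "muscle")))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '<Points>',
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(apply(mesh$nodes, 1, function(r) paste(num_fmt(r), collapse = " ")),
          collapse = "\n"))
  w('</DataArray>', '</Points>', '<Cells>',
    '<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(apply(mesh$cells - 1L, 1, paste, collapse = " "), collapse = "\n"))
  w('</DataArray>',
    '<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 4L, collapse = " "))
  w('</DataArray>', '<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray>', '</Cells>', '<PointData>',
    '<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  w(paste(apply(U, 1, function(r) paste(num_fmt(r), collapse = " ")),
          collapse = "\n"))
  w('</DataArray>', '</PointData>', '<CellData>',
    '<DataArray type="Int32" Name="region" format="ascii">')
  w(paste(reg, collapse = " "))
  w('</DataArray>', '<DataArray type="Float64" Name="Je" format="ascii">')
  w(paste(num_fmt(Je), collapse = " "))
  w('</DataArray>', '<DataArray type="Float64" Name="psi" format="ascii">')
  w(paste(num_fmt(psi), collapse = " "))
  w('</DataArray>', '</CellData>', '</Piece>', '</UnstructuredGrid>',
    '</VTKFile>')
  invisible(path)
}

#' Read back a VTU file written by [write_vtu()]
#' @param path a `.vtu` path.
#' @return list with `n_points`, `n_cells`, `point_fields`, `cell_fields`,
#'   `points`, `cells`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  n <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  m <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  pf <- xml2::xml_attr(
    xml2::xml_find_all(piece, "./PointData/DataArray"), "Name")
  cf <- xml2::xml_attr(
    xml2::xml_find_all(piece, "./CellData/DataArray"), "Name")
  pts <- scan(text = xml2::xml_text(
    xml2::xml_find_first(piece, "./Points/DataArray")), quiet = TRUE)
  conn <- scan(text = xml2::xml_text(xml2::xml_find_first(
    piece, "./Cells/DataArray[@Name='connectivity']")), quiet = TRUE)
  list(n_points = n, n_cells = m, point_fields = pf, cell_fields = cf,
       points = matrix(pts, ncol = 3L, byrow = TRUE),
       cells = matrix(as.integer(conn) + 1L, ncol = 4L, byrow = TRUE))
}

#' Write one increment snapshot and update the series index
#'
#' Writes `increment_%03d.vtu` for the given increment into `dir` and
#' rewrites `series.pvd` to list every snapshot present, in increment order.
#'
#' @param mesh a `tet_mesh`.
#' @param state displacement state for the increment (`NULL` for increment 0).
#' @param increment non-negative integer.
#' @param dir output directory (created if needed).
#' @param time load fraction recorded in the PVD index (defaults to the
#'   increment number).
#' @return path of the VTU file, invisibly.
#' @export
write_snapshot <- function(mesh, state, increment, dir, time = increment) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("increment_%03d.vtu", increment)
  write_vtu(mesh, state, file.path(dir, fn))
  idx_file <- file.path(dir, "snapshot_index.csv")
  idx <- if (file.exists(idx_file))
    utils::read.csv(idx_file, stringsAsFactors = FALSE)
  else data.frame(increment = integer(0), file = character(0),
                  time = numeric(0))
  idx <- idx[idx$increment != increment, , drop = FALSE]
  idx <- rbind(idx, data.frame(increment = increment, file = fn, time = time))
  idx <- idx[order(idx$increment), , drop = FALSE]
  utils::write.csv(idx, idx_file, row.names = FALSE)
  write_pvd(idx$file, idx$time, file.path(dir, "series.pvd"))
  invisible(file.path(dir, fn))
}

#' Write a ParaView PVD collection index
#' @param files VTU file names (relative to the PVD location).
#' @param times time/load values, same length.
#' @param path output `.pvd` path.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(files, times, path) {
  stopifnot(length(files) == length(times))
  lines <- c('<?xml version="1.0"?>',
             '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
             '<Collection>',
             sprintf('<DataSet timestep="%s" group="" part="0" file="%s"/>',
                     num_fmt(times), files),
             '</Collection>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a mesh to Gmsh MSH 4.1 (ASCII)
#'
#' Physical groups: surfaces `"luminal"` (1) and `"external"` (2), volumes
#' `"epithelium"` (3) and `"muscle"` (4).
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.msh` path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  bb <- rbind(apply(mesh$nodes, 2, min), apply(mesh$nodes, 2, max))
  ent <- function(tag, phys) paste(tag, paste(num_fmt(c(bb[1, ], bb[2, ])),
                                              collapse = " "), 1, phys, 0)
  epi <- mesh$cells[mesh$region == "epithelium", , drop = FALSE]
  mus <- mesh$cells[mesh$region == "muscle", , drop = FALSE]
  lum <- mesh$facets$luminal
  ext <- mesh$facets$external
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", "4",
    '2 1 "luminal"', '2 2 "external"',
    '3 3 "epithelium"', '3 4 "muscle"',
    "$EndPhysicalNames")
  w("$Entities", "0 0 2 2", ent(1, 1), ent(2, 2), ent(1, 3), ent(2, 4),
    "$EndEntities")
  w("$Nodes", paste(1, n, 1, n), paste(3, 1, 0, n))
  w(paste(seq_len(n)))
  w(apply(mesh$nodes, 1, function(r) paste(num_fmt(r), collapse = " ")))
  w("$EndNodes")
  blocks <- list(list(dim = 2, tag = 1, type = 2, el = lum),
                 list(dim = 2, tag = 2, type = 2, el = ext),
                 list(dim = 3, tag = 1, type = 4, el = epi),
                 list(dim = 3, tag = 2, type = 4, el = mus))
  blocks <- Filter(function(b) nrow(b$el) > 0, blocks)
  ntot <- sum(vapply(blocks, function(b) nrow(b$el), 1L))
  w("$Elements", paste(length(blocks), ntot, 1, ntot))
  id <- 0L
  for (b in blocks) {
    w(paste(b$dim, b$tag, b$type, nrow(b$el)))
    w(paste(id + seq_len(nrow(b$el)),
            apply(b$el, 1, paste, collapse = " ")))
    id <- id + nrow(b$el)
  }
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 4.1 (ASCII) mesh
#'
#' Reads the subset of MSH 4.1 written by [write_msh()] (and by external
#' meshers using the same physical-group names): triangles tagged `luminal` /
#' `external`, tetrahedra tagged `epithelium` / `muscle`.
#'
#' @param path a `.msh` path.
#' @return a `tet_mesh`.
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), ln)
    i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1)) stop("msh file lacks section $", name)
    ln[(i0 + 1L):(i1 - 1L)]
  }
  # physical names
  pn <- sect("PhysicalNames")
  npn <- as.integer(pn[1])
  phys <- list()
  for (k in seq_len(npn)) {
    parts <- strsplit(trimws(pn[k + 1L]), "\\s+")[[1]]
    phys[[paste(parts[1], parts[2])]] <- gsub('"', "", paste(
      parts[-(1:2)], collapse = " "))
  }
  # entity tag -> physical tag
  en <- sect("Entities")
  counts <- as.integer(strsplit(trimws(en[1]), "\\s+")[[1]])
  ent_phys <- list()
  row <- 2L
  for (dim in 0:3) {
    for (k in seq_len(counts[dim + 1L])) {
      parts <- as.numeric(strsplit(trimws(en[row]), "\\s+")[[1]])
      tag <- as.integer(parts[1])
      off <- if (dim == 0) 4L else 7L   # point entities have 3 coords
      nphys <- as.integer(parts[off + 1L])
      if (nphys >= 1L)
        ent_phys[[paste(dim, tag)]] <- as.integer(parts[off + 2L])
      row <- row + 1L
    }
  }
  # nodes
  nd <- sect("Nodes")
  hdr <- as.numeric(strsplit(trimws(nd[1]), "\\s+")[[1]])
  nblocks <- hdr[1]; nnodes <- hdr[2]; maxtag <- hdr[4]
  coords <- matrix(NA_real_, maxtag, 3L)
  row <- 2L
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(nd[row]), "\\s+")[[1]])
    nb <- bh[4]; row <- row + 1L
    tags <- as.integer(nd[row:(row + nb - 1L)]); row <- row + nb
    for (k in seq_len(nb)) {
      coords[tags[k], ] <- as.numeric(
        strsplit(trimws(nd[row]), "\\s+")[[1]])[1:3]
      row <- row + 1L
    }
  }
  # elements
  el <- sect("Elements")
  hdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
  cells <- list(); regions <- list(); tris <- list(); tri_phys <- list()
  row <- 2L
  for (b in seq_len(hdr[1])) {
    bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
    dim <- bh[1]; tag <- bh[2]; type <- bh[3]; nb <- bh[4]
    row <- row + 1L
    dat <- do.call(rbind, lapply(el[row:(row + nb - 1L)], function(s)
      as.integer(strsplit(trimws(s), "\\s+")[[1]])))
    row <- row + nb
    pname <- phys[[paste(dim, ent_phys[[paste(dim, tag)]])]]
    if (type == 4L) {
      cells[[length(cells) + 1L]] <- dat[, 2:5, drop = FALSE]
      regions[[length(regions) + 1L]] <- rep(pname, nb)
    } else if (type == 2L) {
      tris[[length(tris) + 1L]] <- dat[, 2:4, drop = FALSE]
      tri_phys[[length(tri_phys) + 1L]] <- rep(pname, nb)
    }
  }
  cells <- do.call(rbind, cells)
  region <- unlist(regions)
  tri <- do.call(rbind, tris)
  tph <- unlist(tri_phys)
  used <- sort(unique(as.vector(cells)))
  remap <- integer(nrow(coords)); remap[used] <- seq_along(used)
  mesh <- structure(list(nodes = coords[used, , drop = FALSE],
                         cells = matrix(remap[cells], ncol = 4L),
                         region = region,
                         facets = list(
                           luminal = matrix(remap[tri[tph == "luminal", ,
                                                      drop = FALSE]],
                                            ncol = 3L),
                           external = matrix(remap[tri[tph == "external", ,
                                                       drop = FALSE]],
                                             ncol = 3L)),
                         meta = list(source = path)),
                    class = "tet_mesh")
  vol <- tet_volumes(mesh)
  neg <- which(vol < 0)
  if (length(neg)) mesh$cells[neg, 3:4] <- mesh$cells[neg, 4:3]
  mesh
}

#' Write morphometry tables and summary
#'
#' Writes `protrusions.csv` (per hole), `thickness.csv` (per luminal facet)
#' and `morphometry.json` (summary statistics) into `dir`. Output is
#' byte-deterministic for identical inputs.
#'
#' @param report a `morphometry_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_morphometry <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$protrusions,
                   file.path(dir, "protrusions.csv"), row.names = FALSE)
  th <- data.frame(facet = seq_along(report$thickness_initial$thickness),
                   thickness_initial = report$thickness_initial$thickness,
                   thickness_final = report$thickness_final$thickness)
  utils::write.csv(th, file.path(dir, "thickness.csv"), row.names = FALSE)
  summ <- list(
    aspect_ratio = report$aspect_ratio,
    aspect_ratio_reference = report$aspect_ratio_reference,
    thickness_initial_mean = report$thickness_initial$mean,
    thickness_initial_sd = report$thickness_initial$sd,
    thickness_final_mean = report$thickness_final$mean,
    thickness_final_sd = report$thickness_final$sd,
    thickness_rays_missed = report$thickness_final$n_missed,
    thinning_ratio = report$thinning_ratio,
    n_holes = nrow(report$protrusions),
    protrusion_min = if (nrow(report$protrusions))
      min(report$protrusions$amplitude) else NA,
    protrusion_mean = if (nrow(report$protrusions))
      mean(report$protrusions$amplitude) else NA)
  jsonlite::write_json(summ, file.path(dir, "morphometry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# full per-run output bundle: resolved config, VTU series + PVD, reports
write_run_outputs <- function(mesh, state, report, config) {
  dir <- config$output_dir
  save_config(config, file.path(dir, "config.yaml"))
  files <- character(0); times <- numeric(0)
  write_vtu(mesh, NULL, file.path(dir, "increment_000.vtu"))
  files <- "increment_000.vtu"; times <- 0
  for (k in seq_along(state$increments)) {
    inc <- state$increments[[k]]
    f <- sprintf("increment_%03d.vtu", k)
    write_vtu(mesh, inc$u, file.path(dir, f))
    files <- c(files, f); times <- c(times, inc$s)
  }
  write_pvd(files, times, file.path(dir, "series.pvd"))
  write_morphometry(report, dir)
  utils::write.csv(state$history, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  invisible(dir)
}
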