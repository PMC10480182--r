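#' Generate a body-fitted structured mesh for a stenosis geometry
#'
#' Builds an `ni x nj` structured grid conforming exactly to the wall
#' contour. Grid columns are planes of constant axial station, so cut planes
#' placed on a column need no geometric interpolation when a sub-model is
#' extracted. Transverse node spacing follows a geometric progression
#' clustered toward the walls with the given stretch ratio.
#'
#' In `"planar"` mode the domain spans the full channel (two walls at
#' `y = +/- h(x)`, `nj` must be even). In `"axisymmetric"` mode `y` is the
#' radius: the lower boundary `y = 0` is the symmetry axis and the single
#' wall sits at `y = h(x)`; face areas and cell volumes are per radian.
#'
#' @param geometry a [build_geometry()] object.
#' @param ni,nj number of cells in the axial and transverse directions
#'   (both at least 8).
#' @param wall_stretch_ratio geometric growth ratio of transverse cell
#'   heights away from the wall (`>= 1`; 1 gives uniform spacing).
#' @param mode `"planar"` or `"axisymmetric"`.
#' @param stations optional numeric vector of axial positions (m) that must
#'   coincide exactly with grid columns (e.g. cut planes). When given, the
#'   axial distribution is piecewise uniform between consecutive stations.
#' @param refine_range optional length-2 numeric: axial interval whose
#'   segments receive `refine_factor` times the base axial cell density.
#' @param refine_factor axial refinement multiplier inside `refine_range`.
#' @return an object of class `structured_mesh`.
#' @export
generate_mesh <- function(geometry, ni, nj, wall_stretch_ratio = 1,
                          mode = c("planar", "axisymmetric"),
                          stations = NULL, refine_range = NULL,
                          refine_factor = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "stenosis_geometry"))
  if (ni < 8 || nj < 8) stop("ni and nj must both be at least 8")
  if (wall_stretch_ratio < 1) stop("wall_stretch_ratio must be >= 1")
  if (mode == "planar" && nj %% 2 != 0)
    stop("planar mode requires an even nj (symmetric two-sided clustering)")
  if (mode == "axisymmetric" && geometry$bend_angle != 0)
    stop("the in-plane bend is only available in planar mode")

  L <- geometry$total_length
  xcol <- axial_distribution(L, ni, stations, refine_range, refine_factor)
  tbrk <- transverse_distribution(nj, wall_stretch_ratio, mode)
  h <- wall_halfwidth(geometry, xcol)
  xn <- matrix(xcol, ni + 1, nj + 1)
  yn <- outer(h, tbrk)
  if (geometry$bend_angle != 0) {
    th <- geometry$bend_angle * pi / 180
    x1 <- geometry$stenosis_end
    past <- xn > x1 + 1e-12
    s <- xn[past] - x1
    y <- yn[past]
    xn[past] <- x1 + s * cos(th) - y * sin(th)
    yn[past] <- s * sin(th) + y * cos(th)
  }
  new_structured_mesh(xn, yn, xcol, tbrk, geometry, mode, wall_stretch_ratio)
}

new_structured_mesh <- function(xn, yn, axial_station, tbrk, geometry, mode,
                                wall_stretch_ratio) {
  ni <- nrow(xn) - 1
  nj <- ncol(xn) - 1
  gm <- cpp_cell_geometry(xn, yn, if (mode == "axisymmetric") 1L else 0L)
  mesh <- structure(list(
    xn = xn, yn = yn, ni = ni, nj = nj, mode = mode,
    axial_station = axial_station, tbrk = tbrk,
    geometry = geometry, wall_stretch_ratio = wall_stretch_ratio,
    cell_volume = gm$volume, cell_cx = gm$cx, cell_cy = gm$cy,
    inlet_face_areas = gm$inlet_face_areas
  ), class = "structured_mesh")
  mesh
}

# piecewise-uniform axial node distribution honouring required stations
axial_distribution <- function(L, ni, stations, refine_range, refine_factor) {
  if (is.null(stations)) return(seq(0, L, length.out = ni + 1))
  brk <- sort(unique(c(0, stations[stations > 1e-12 & stations < L - 1e-12], L)))
  len <- diff(brk)
  w <- rep(1, length(len))
  if (!is.null(refine_range)) {
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    w[mid >= refine_range[1] & mid <= refine_range[2]] <- refine_factor
  }
  raw <- ni * len * w / sum(len * w)
  n <- pmax(1L, round(raw))
  while (sum(n) != ni) { # nudge the largest segments to hit the total exactly
    k <- if (sum(n) > ni) which.max(n - raw) else which.min(n - raw)
    n[k] <- n[k] + if (sum(n) > ni) -1L else 1L
    if (any(n < 1)) stop("ni too small for the requested station set")
  }
  x <- 0
  for (s in seq_along(len))
    x <- c(x, seq(brk[s], brk[s + 1], length.out = n[s] + 1)[-1])
  x
}

# normalized transverse node fractions: [-1, 1] planar, [0, 1] axisymmetric,
# geometric clustering toward the wall(s)
transverse_distribution <- function(nj, r, mode) {
  geom_breaks <- function(m, r) {
    # m cell heights growing from the wall with ratio r, normalized to sum 1
    if (r == 1) rep(1 / m, m) else (r - 1) / (r^m - 1) * r^(0:(m - 1))
  }
  if (mode == "planar") {
    m <- nj / 2
    d <- geom_breaks(m, r)
    heights <- c(d, rev(d)) # wall -> centre -> wall
    cum <- cumsum(c(0, heights))
    -1 + 2 * cum / cum[length(cum)]
  } else {
    d <- geom_breaks(nj, r) # sizes from the wall inward
    heights <- rev(d)       # axis -> wall
    cum <- cumsum(c(0, heights))
    cum / cum[length(cum)]
  }
}

#' Extract a sub-model mesh at a cut plane
#'
#' Slices the full-model mesh at the grid column coinciding with the cut
#' plane. The sub-model inlet boundary is node-for-node identical to that
#' column of the full mesh, so profile mapping needs no interpolation in the
#' default configuration.
#'
#' @param full_mesh a `structured_mesh` of the full model.
#' @param cut a [cut_plane()] (or numeric axial position in metres).
#' @return a `structured_mesh` covering axial stations at and beyond the
#'   cut, with attribute `cut_offset` giving the cut position.
#' @export
extract_submodel_mesh <- function(full_mesh, cut) {
  stopifnot(inherits(full_mesh, "structured_mesh"))
  pos <- if (inherits(cut, "cut_plane")) cut$axial_position else as.numeric(cut)
  L <- full_mesh$geometry$total_length
  if (pos >= L) stop("cut plane lies at or beyond the outlet")
  if (pos < 0) stop("cut plane lies upstream of the inlet")
  ic <- cut_column_index(full_mesh, pos)
  idx <- ic:(full_mesh$ni + 1)
  mesh <- new_structured_mesh(full_mesh$xn[idx, , drop = FALSE],
                              full_mesh$yn[idx, , drop = FALSE],
                              full_mesh$axial_station[idx], full_mesh$tbrk,
                              full_mesh$geometry, full_mesh$mode,
                              full_mesh$wall_stretch_ratio)
  attr(mesh, "cut_offset") <- full_mesh$axial_station[ic]
  mesh
}

# 1-based node-column index whose axial station matches pos
cut_column_index <- function(mesh, pos) {
  tol <- 1e-9 * max(mesh$geometry$total_length, 1)
  ic <- which(abs(mesh$axial_station - pos) <= tol)
  if (length(ic) != 1)
    stop(sprintf(paste0("cut plane at x = %g does not coincide with a mesh grid ",
                        "column; pass it via `stations` when generating the mesh"),
                 pos))
  ic
}

#' Mesh accessors
#'
#' `mesh_cell_centers` returns the cell-centroid coordinates, ordered
#' column-major `(i, j)`; `mesh_cell_areas` the cell areas (planar) or
#' per-radian volumes (axisymmetric); `mesh_total_area` their sum;
#' `inlet_face_areas` the per-face inlet areas (per-unit-depth lengths for
#' planar, per-radian annular areas for axisymmetric); `wall_distance` the
#' per-cell normal distance to the nearest wall.
#'
#' @param mesh a `structured_mesh`.
#' @return numeric matrices/vectors of the requested quantity.
#' @export
mesh_cell_centers <- function(mesh) {
  stopifnot(inherits(mesh, "structured_mesh"))
  list(x = mesh$cell_cx, y = mesh$cell_cy)
}

#' @rdname mesh_cell_centers
#' @export
mesh_cell_areas <- function(mesh) {
  stopifnot(inherits(mesh, "structured_mesh"))
  if (mesh$mode == "axisymmetric") {
    # shoelace areas (volumes are radius-weighted); recompute plain areas
    m <- mesh
    gm <- cpp_cell_geometry(m$xn, m$yn, 0L)
    gm$volume
  } else mesh$cell_volume
}

#' @rdname mesh_cell_centers
#' @export
mesh_total_area <- function(mesh) sum(mesh_cell_areas(mesh))

#' @rdname mesh_cell_centers
#' @export
inlet_face_areas <- function(mesh) {
  stopifnot(inherits(mesh, "structured_mesh"))
  mesh$inlet_face_areas
}

#' @rdname mesh_cell_centers
#' @export
wall_distance <- function(mesh) {
  stopifnot(inherits(mesh, "structured_mesh"))
  geo <- mesh$geometry
  xmid <- (mesh$axial_station[-1] + mesh$axial_station[-(mesh$ni + 1)]) / 2
  h <- wall_halfwidth(geo, xmid)
  # wall slope correction: normal distance = vertical gap * cos(atan(h'))
  dh <- diff(wall_halfwidth(geo, mesh$axial_station)) /
    pmax(diff(mesh$axial_station), 1e-300)
  cosa <- 1 / sqrt(1 + dh^2)
  tmid <- (mesh$tbrk[-1] + mesh$tbrk[-(mesh$nj + 1)]) / 2
  gap <- outer(h, if (mesh$mode == "planar") 1 - abs(tmid) else 1 - tmid)
  gap * cosa
}

#' @export
print.structured_mesh <- function(x, ...) {
  cat(sprintf("Structured mesh: %d x %d cells (%s)\n", x$ni, x$nj, x$mode))
  cat(sprintf("  axial extent [%g, %g] m, wall stretch ratio %g\n",
              min(x$axial_station), max(x$axial_station), x$wall_stretch_ratio))
  invisible(x)
}

#' Export a mesh (and optional cell fields) as a legacy VTK file
#'
#' Writes an ASCII VTK structured grid for visualization in ParaView etc.
#'
#' @param mesh a `structured_mesh`.
#' @param path output file path.
#' @param fields optional named list of `ni x nj` matrices written as cell
#'   data.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, fields = list()) {
  stopifnot(inherits(mesh, "structured_mesh"))
  ni <- mesh$ni; nj <- mesh$nj
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stenoflow structured mesh",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", ni + 1, nj + 1),
               sprintf("POINTS %d double", (ni + 1) * (nj + 1))), con)
  pts <- cbind(as.vector(mesh$xn), as.vector(mesh$yn), 0)
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 12), collapse = " ")), con)
  if (length(fields)) {
    writeLines(sprintf("CELL_DATA %d", ni * nj), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.vector(fields[[nm]]), digits = 12), con)
    }
  }
  invisible(path)
}
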