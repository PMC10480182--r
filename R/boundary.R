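#' Inlet turbulent kinetic energy from turbulence intensity
#'
#' `k = (3/2) (U I)^2`: the isotropic estimate of the inlet TKE given a mean
#' velocity `U` and turbulence intensity `I` (RMS fluctuation over mean).
#'
#' @param U mean flow velocity, m/s (non-negative).
#' @param I turbulence intensity, dimensionless (non-negative).
#' @return k in m^2/s^2.
#' @examples
#' k_from_intensity(0.66, 0.05) # 0.0016335
#' @export
k_from_intensity <- function(U, I) {
  if (any(U < 0) || any(I < 0)) stop("U and I must be non-negative")
  1.5 * (U * I)^2
}

#' Turbulence intensity of fully developed duct flow
#'
#' The core turbulence intensity of a fully developed duct flow,
#' `I = 0.16 Re^(-1/8)`, with the Reynolds number based on the hydraulic
#' diameter. Strictly decreasing in `Re`.
#'
#' @param Re_dh Reynolds number (positive).
#' @return intensity, dimensionless.
#' @examples
#' intensity_from_reynolds(4000) # ~ 0.0567
#' @export
intensity_from_reynolds <- function(Re_dh) {
  if (any(Re_dh <= 0)) stop("Reynolds number must be positive")
  0.16 * Re_dh^(-1 / 8)
}

#' Inlet dissipation rate from a mixing length
#'
#' The mixing-length dissipation relation `eps = C_mu^(3/4) k^(3/2) / l`.
#'
#' @param k turbulent kinetic energy, m^2/s^2 (non-negative).
#' @param l mixing length, m (positive).
#' @param c_mu model constant (0.09).
#' @return eps in m^2/s^3; zero iff `k` is zero.
#' @export
eps_from_mixing_length <- function(k, l, c_mu = KE_CONSTANTS$c_mu) {
  if (any(k < 0)) stop("k must be non-negative")
  if (any(l <= 0)) stop("mixing length must be positive")
  c_mu^0.75 * k^1.5 / l
}

#' Inlet boundary specification
#'
#' Describes the inlet state fed to the solver: per-inlet-face normal
#' velocity and TKE profiles plus a mixing length that converts the TKE into
#' a dissipation rate. Two modes exist: `uniform_TI` (constant velocity and
#' `k = (3/2)(U I)^2`) and `mapped_profile` (profiles extracted from a
#' ground-truth solution, possibly degraded).
#'
#' @param velocity per-face normal velocity, m/s.
#' @param k per-face TKE, m^2/s^2 (recycled if scalar).
#' @param mixing_length mixing length in m used for the dissipation profile.
#' @param mode `"uniform_TI"` or `"mapped_profile"`.
#' @param intensity the turbulence intensity (stored for provenance in
#'   `uniform_TI` mode).
#' @return an object of class `inlet_spec` with an `eps` profile computed
#'   pointwise from `k` and the mixing length.
#' @export
inlet_spec <- function(velocity, k, mixing_length,
                       mode = c("mapped_profile", "uniform_TI"),
                       intensity = NA_real_) {
  mode <- match.arg(mode)
  if (!all(is.finite(velocity))) stop("velocity profile must be finite")
  if (any(k < 0)) stop("k profile must be non-negative")
  if (mixing_length <= 0) stop("mixing length must be positive")
  if (length(k) == 1) k <- rep(k, length(velocity))
  if (length(k) != length(velocity))
    stop("velocity and k profiles must have equal length")
  structure(list(mode = mode, velocity = as.numeric(velocity),
                 k = as.numeric(k),
                 eps = eps_from_mixing_length(as.numeric(k), mixing_length),
                 mixing_length = mixing_length, intensity = intensity),
            class = "inlet_spec")
}

#' @export
print.inlet_spec <- function(x, ...) {
  cat(sprintf("Inlet spec (%s): %d faces\n", x$mode, length(x$velocity)))
  cat(sprintf("  velocity [%.4g, %.4g] m/s; k [%.4g, %.4g] m2/s2; l = %g m\n",
              min(x$velocity), max(x$velocity), min(x$k), max(x$k),
              x$mixing_length))
  invisible(x)
}

#' Extract a velocity/TKE profile on a cut plane
#'
#' Samples the converged full-model solution on a grid-column cut plane: the
#' plane-normal velocity is recovered from the face mass fluxes (so the
#' profile's integrated mass flux equals the solver's flux through that
#' station exactly) and the TKE is interpolated to the face midpoints.
#'
#' @param flow a converged `flow_field` on the full-model mesh.
#' @param mesh the full-model `structured_mesh`.
#' @param cut a [cut_plane()] (or axial position in metres) lying on a grid
#'   column strictly inside the domain.
#' @return an object of class `plane_profile`: transverse positions (m),
#'   normal velocity (m/s), TKE (m^2/s^2), face areas, and the source
#'   station label.
#' @export
extract_plane_profile <- function(flow, mesh, cut) {
  stopifnot(inherits(flow, "flow_field"), inherits(mesh, "structured_mesh"))
  pos <- if (inherits(cut, "cut_plane")) cut$axial_position else as.numeric(cut)
  label <- if (inherits(cut, "cut_plane")) cut$station_label else sprintf("x=%g", pos)
  ic <- cut_column_index(mesh, pos)
  if (ic > mesh$ni) stop("cut plane lies on the outlet boundary")
  if (!flow$converged)
    warning("extracting a profile from an unconverged flow field", call. = FALSE)
  nj <- mesh$nj
  yc <- (mesh$yn[ic, -1] + mesh$yn[ic, -(nj + 1)]) / 2
  dy <- mesh$yn[ic, -1] - mesh$yn[ic, -(nj + 1)]
  area <- if (mesh$mode == "axisymmetric") {
    (mesh$yn[ic, -1] + mesh$yn[ic, -(nj + 1)]) / 2 * dy # per radian
  } else dy
  if (ic == 1) {
    vel <- flow$inlet$velocity
    kf <- flow$inlet$k
  } else {
    # ic is a node column => x-face index ic-1 (0-based) between cell
    # columns ic-1 and ic (1-based); mx rows are faces
    vel <- flow$mx[ic, ] / (flow$fluid$rho * area)
    if (ic <= mesh$ni) {
      kf <- (flow$k[ic - 1, ] + flow$k[ic, ]) / 2
    } else kf <- flow$k[mesh$ni, ]
  }
  structure(list(positions = as.numeric(yc), velocity = as.numeric(vel),
                 k = pmax(as.numeric(kf), 0), face_areas = as.numeric(area),
                 lumen = range(mesh$yn[ic, ]),
                 diameter_ref = mesh$geometry$diameter_D,
                 station_label = label, axial_position = pos),
            class = "plane_profile")
}

#' Mass flux carried by a plane profile
#'
#' @param profile a `plane_profile`.
#' @param rho fluid density, kg/m^3.
#' @return integrated mass flux (kg/s per unit depth, or per radian in
#'   axisymmetric mode).
#' @export
profile_mass_flux <- function(profile, rho = 1) {
  stopifnot(inherits(profile, "plane_profile"))
  rho * sum(profile$velocity * profile$face_areas)
}

#' Map a plane profile onto a sub-model inlet
#'
#' Builds a `mapped_profile` inlet spec from an extracted (or degraded)
#' plane profile. When the sub-model inlet face midpoints coincide with the
#' profile positions the mapping is exact (bit-identical values); otherwise
#' the profile is linearly interpolated in the transverse coordinate and the
#' velocity is rescaled by a uniform factor so the mapped mass flux matches
#' the profile's. Extrapolation beyond the profile's lumen is an error.
#' The dissipation profile is computed pointwise from the mapped TKE and the
#' sub-model mixing length.
#'
#' @param profile a `plane_profile`.
#' @param submesh the sub-model `structured_mesh`.
#' @param mixing_length sub-model mixing length in m.
#' @param k_override optional per-face TKE profile replacing the profile's
#'   (used for degraded reconstructions).
#' @return an [inlet_spec()] in `mapped_profile` mode.
#' @export
map_profile_to_inlet <- function(profile, submesh, mixing_length,
                                 k_override = NULL) {
  stopifnot(inherits(profile, "plane_profile"),
            inherits(submesh, "structured_mesh"))
  nj <- submesh$nj
  yt <- (submesh$yn[1, -1] + submesh$yn[1, -(nj + 1)]) / 2
  ksrc <- k_override %||% profile$k
  if (length(yt) == length(profile$positions) &&
      max(abs(yt - profile$positions)) <= 1e-12 * max(abs(profile$lumen))) {
    vel <- profile$velocity
    kk <- ksrc
  } else {
    if (min(yt) < min(profile$lumen) - 1e-12 ||
        max(yt) > max(profile$lumen) + 1e-12)
      stop("profile lumen is narrower than the sub-model inlet (extrapolation)")
    vel <- approx(profile$positions, profile$velocity, xout = yt, rule = 2)$y
    kk <- approx(profile$positions, ksrc, xout = yt, rule = 2)$y
    dy <- submesh$yn[1, -1] - submesh$yn[1, -(nj + 1)]
    area <- if (submesh$mode == "axisymmetric")
      (submesh$yn[1, -1] + submesh$yn[1, -(nj + 1)]) / 2 * dy else dy
    target <- sum(profile$velocity * profile$face_areas)
    got <- sum(vel * area)
    if (abs(got) > 0) vel <- vel * target / got
  }
  inlet_spec(vel, pmax(kk, 0), mixing_length, mode = "mapped_profile")
}

#' Uniform turbulence-intensity inlet
#'
#' A fully uniform inlet: constant velocity `U` and constant
#' `k = (3/2)(U I)^2` on every inlet face.
#'
#' @param U uniform inlet velocity, m/s (positive).
#' @param I turbulence intensity (e.g. 0.05, 0.10, 0.15).
#' @param mixing_length mixing length in m.
#' @param submesh the target `structured_mesh` (sets the face count).
#' @return an [inlet_spec()] in `uniform_TI` mode.
#' @export
build_uniform_ti_inlet <- function(U, I, mixing_length, submesh) {
  stopifnot(inherits(submesh, "structured_mesh"))
  if (U <= 0) stop("U must be positive")
  inlet_spec(rep(U, submesh$nj), k_from_intensity(U, I), mixing_length,
             mode = "uniform_TI", intensity = I)
}

#' Turbulence-intensity inlet anchored to an extracted profile
#'
#' Builds the turbulence-intensity variant used in the boundary-condition
#' comparison: the turbulence quantities come from the intensity (constant
#' `k = (3/2)(U_mean I)^2` with `U_mean` the area-averaged profile
#' velocity), while the velocity is either the mapped profile (default, so
#' mass flux and velocity boundary data are identical across compared
#' cases and only the turbulence boundary condition differs) or uniform at
#' `U_mean` (`uniform_velocity = TRUE`), which preserves the mass flux
#' exactly by construction.
#'
#' @param profile a `plane_profile`.
#' @param I turbulence intensity.
#' @param mixing_length mixing length in m.
#' @param submesh the sub-model `structured_mesh`.
#' @param uniform_velocity logical; use a flat velocity profile instead of
#'   the mapped one.
#' @return an [inlet_spec()] in `uniform_TI` mode.
#' @export
ti_inlet_from_profile <- function(profile, I, mixing_length, submesh,
                                  uniform_velocity = FALSE) {
  stopifnot(inherits(profile, "plane_profile"))
  Umean <- sum(profile$velocity * profile$face_areas) / sum(profile$face_areas)
  kTI <- k_from_intensity(abs(Umean), I)
  if (uniform_velocity) {
    sp <- inlet_spec(rep(Umean, submesh$nj), kTI, mixing_length,
                     mode = "uniform_TI", intensity = I)
  } else {
    sp <- map_profile_to_inlet(profile, submesh, mixing_length,
                               k_override = rep(kTI, length(profile$k)))
    sp$mode <- "uniform_TI"
    sp$intensity <- I
  }
  sp
}

#' Serialize a plane profile to CSV (+ JSON sidecar)
#'
#' Writes `position`, `velocity`, `k` and `face_area` columns to `path` and
#' station metadata to `<path>.json`.
#'
#' @param profile a `plane_profile`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_plane_profile <- function(profile, path) {
  stopifnot(inherits(profile, "plane_profile"))
  df <- data.frame(position = profile$positions, velocity = profile$velocity,
                   k = profile$k, face_area = profile$face_areas)
  write.csv(df, path, row.names = FALSE)
  meta <- list(station_label = profile$station_label,
               axial_position = profile$axial_position,
               lumen = profile$lumen, diameter_ref = profile$diameter_ref)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane_profile
#' @export
read_plane_profile <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(positions = df$position, velocity = df$velocity, k = df$k,
                 face_areas = df$face_area, lumen = as.numeric(meta$lumen),
                 diameter_ref = meta$diameter_ref,
                 station_label = meta$station_label,
                 axial_position = meta$axial_position),
            class = "plane_profile")
}
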