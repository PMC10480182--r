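#' Parametric stenosis-channel geometry
#'
#' Builds a planar (or axisymmetric) channel of reference diameter `D` with a
#' smooth symmetric constriction. The severity is the fraction of the
#' diameter occluded at the throat, so the throat width is `(1 - severity) *
#' D`. Axial lengths are given in multiples of `D`: an inlet run, the
#' stenosis segment, and an outlet run. The wall contour is C1-continuous
#' (cosine bump by default). An optional in-plane bend, applied rigidly
#' downstream of the stenosis, is available via `bend_angle`.
#'
#' @param diameter_D reference (unconstricted) diameter in metres.
#' @param severity fraction of the diameter occluded at the throat, in
#'   `[0, 1)`. `0` gives a straight duct.
#' @param inlet_run,stenosis_length,outlet_run axial lengths in multiples of
#'   `diameter_D`.
#' @param bend_angle in-plane bend angle in degrees applied downstream of the
#'   stenosis segment (default 0, straight).
#' @param throat_profile wall shape of the constriction: `"cosine"` (default)
#'   or `"smooth-step"` (cubic smoothstep ramps).
#' @return an object of class `stenosis_geometry`.
#' @examples
#' geo <- build_geometry(0.02, 0.5, 6, 2, 8)
#' wall_halfwidth(geo, 0.14)  # throat half-width: 0.005 m
#' @export
build_geometry <- function(diameter_D, severity, inlet_run, stenosis_length,
                           outlet_run, bend_angle = 0,
                           throat_profile = c("cosine", "smooth-step")) {
  throat_profile <- match.arg(throat_profile)
  if (!is.numeric(diameter_D) || diameter_D <= 0)
    stop("diameter_D must be positive")
  if (!is.numeric(severity) || severity < 0)
    stop("severity must be a fraction in [0, 1)")
  if (severity >= 1)
    stop("degenerate geometry: severity >= 1 closes the lumen")
  if (any(c(inlet_run, stenosis_length, outlet_run) <= 0))
    stop("inlet_run, stenosis_length and outlet_run must be positive")
  geo <- structure(list(
    diameter_D = diameter_D, severity = severity,
    inlet_run = inlet_run, stenosis_length = stenosis_length,
    outlet_run = outlet_run, bend_angle = bend_angle,
    throat_profile = throat_profile,
    total_length = (inlet_run + stenosis_length + outlet_run) * diameter_D,
    stenosis_start = inlet_run * diameter_D,
    stenosis_end = (inlet_run + stenosis_length) * diameter_D
  ), class = "stenosis_geometry")
  geo
}

#' Wall half-width of a stenosis geometry
#'
#' Evaluates the channel half-width (wall contour) at axial stations `x`
#' (metres, 0 at the inlet plane, measured along the unbent centreline).
#'
#' @param geometry a `stenosis_geometry`.
#' @param x numeric vector of axial stations in metres.
#' @return half-width in metres; `diameter_D / 2` outside the stenosis
#'   segment, `(1 - severity) * diameter_D / 2` at the apex.
#' @export
wall_halfwidth <- function(geometry, x) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  D <- geometry$diameter_D
  h0 <- D / 2
  amp <- geometry$severity * D / 2 # half-width reduction at the apex
  x0 <- geometry$stenosis_start
  x1 <- geometry$stenosis_end
  t <- (x - x0) / (x1 - x0)
  inside <- t > 0 & t < 1
  shape <- numeric(length(x))
  if (geometry$throat_profile == "cosine") {
    shape[inside] <- 0.5 * (1 - cos(2 * pi * t[inside]))
  } else {
    tt <- t[inside]
    up <- tt <= 0.5
    s <- numeric(length(tt))
    r <- 2 * tt[up]                      # ramp in
    s[up] <- 3 * r^2 - 2 * r^3
    r <- 2 * (1 - tt[!up])               # ramp out
    s[!up] <- 3 * r^2 - 2 * r^3
    shape[inside] <- s
  }
  h0 - amp * shape
}

#' Apex axial station of a stenosis geometry
#'
#' The throat (apex) sits at the midpoint of the stenosis segment,
#' `(inlet_run + stenosis_length / 2) * D`.
#' @param geometry a `stenosis_geometry`.
#' @return axial position in metres.
#' @export
apex_station <- function(geometry) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  (geometry$inlet_run + geometry$stenosis_length / 2) * geometry$diameter_D
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat("Stenosis-channel geometry\n")
  cat(sprintf("  D = %g m, severity = %g%% of diameter (throat width %g m)\n",
              x$diameter_D, 100 * x$severity, (1 - x$severity) * x$diameter_D))
  cat(sprintf("  runs: inlet %gD, stenosis %gD, outlet %gD (total %g m)\n",
              x$inlet_run, x$stenosis_length, x$outlet_run, x$total_length))
  if (x$bend_angle != 0)
    cat(sprintf("  in-plane bend: %g deg downstream of the stenosis\n", x$bend_angle))
  cat(sprintf("  throat profile: %s\n", x$throat_profile))
  invisible(x)
}

#' Define a cut plane of the full model
#'
#' Cut planes mark where sub-models are severed from the full model: at the
#' stenotic apex, or 0.5D / 1.0D distal to it. An arbitrary axial position
#' can also be given directly.
#'
#' @param geometry a `stenosis_geometry`.
#' @param station `"apex"`, `"0.5D"`, `"1.0D"`, or a numeric axial position
#'   in metres.
#' @return an object of class `cut_plane` with the station label and axial
#'   position.
#' @export
cut_plane <- function(geometry, station) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  D <- geometry$diameter_D
  apex <- apex_station(geometry)
  if (is.character(station)) {
    pos <- switch(station,
                  "apex" = apex,
                  "0.5D" = apex + 0.5 * D,
                  "1.0D" = apex + 1.0 * D,
                  stop("unknown station label: ", station))
    label <- station
  } else {
    pos <- as.numeric(station)
    label <- sprintf("x=%g", pos)
  }
  if (pos < 0 || pos > geometry$total_length)
    stop("cut plane lies outside the domain")
  structure(list(station_label = label, axial_position = pos),
            class = "cut_plane")
}
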