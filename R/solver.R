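#' Fluid properties
#'
#' @param density mass density in kg/m^3 (blood: 1060).
#' @param dynamic_viscosity dynamic viscosity in Pa.s (blood: 3.5 cP =
#'   0.0035 Pa.s).
#' @return object of class `fluid_properties` with the derived kinematic
#'   viscosity `nu = mu / rho`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("density and dynamic_viscosity must be positive")
  structure(list(rho = density, mu = dynamic_viscosity,
                 nu = dynamic_viscosity / density),
            class = "fluid_properties")
}

#' Reynolds number of a duct flow
#'
#' `Re = rho * U * D / mu` based on the bulk velocity and (hydraulic)
#' diameter.
#'
#' @param fluid a [fluid_properties()] object.
#' @param velocity bulk velocity in m/s.
#' @param diameter diameter in m.
#' @return the Reynolds number.
#' @examples
#' reynolds_number(fluid_properties(1060, 0.0035), 0.66, 0.02) # ~ 4.0e3
#' @export
reynolds_number <- function(fluid, velocity, diameter) {
  stopifnot(inherits(fluid, "fluid_properties"))
  fluid$rho * velocity * diameter / fluid$mu
}

#' Solver settings for the SIMPLE iteration
#'
#' @param relax_u,relax_p,relax_turb under-relaxation factors for momentum,
#'   pressure correction and the turbulence quantities, in `(0, 1]`.
#' @param max_iterations cap on outer SIMPLE iterations.
#' @param residual_tolerance normalized-residual convergence threshold
#'   applied to every equation (default 1e-4).
#' @param convection_scheme `"second-order-upwind-limited"` (minmod-limited
#'   deferred correction, default) or `"first-order-upwind"`.
#' @param turbulence logical; `FALSE` solves the laminar equations.
#' @param inner_sweeps alternating-direction TDMA sweeps per equation per
#'   outer iteration.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(relax_u = 0.7, relax_p = 0.3, relax_turb = 0.5,
                            max_iterations = 5000, residual_tolerance = 1e-4,
                            convection_scheme = c("second-order-upwind-limited",
                                                  "first-order-upwind"),
                            turbulence = TRUE, inner_sweeps = 2) {
  convection_scheme <- match.arg(convection_scheme)
  if (any(c(relax_u, relax_p, relax_turb) <= 0) ||
      any(c(relax_u, relax_p, relax_turb) > 1))
    stop("relaxation factors must lie in (0, 1]")
  if (residual_tolerance <= 0) stop("residual_tolerance must be positive")
  structure(list(relax_u = relax_u, relax_p = relax_p, relax_turb = relax_turb,
                 max_iterations = as.integer(max_iterations),
                 residual_tolerance = residual_tolerance,
                 convection_scheme = convection_scheme,
                 turbulence = isTRUE(turbulence),
                 inner_sweeps = as.integer(inner_sweeps)),
            class = "solver_settings")
}

settings_for_cpp <- function(settings) {
  list(relax_u = settings$relax_u, relax_p = settings$relax_p,
       relax_turb = settings$relax_turb,
       max_iterations = settings$max_iterations,
       residual_tolerance = settings$residual_tolerance,
       scheme = if (settings$convection_scheme == "first-order-upwind") 0L else 1L,
       turbulence = settings$turbulence,
       inner_sweeps = settings$inner_sweeps)
}

#' Solve the steady incompressible RANS equations
#'
#' SIMPLE pressure-velocity coupling on the colocated structured mesh with
#' Rhie-Chow face interpolation; standard k-epsilon closure with wall
#' functions when turbulence is enabled. Boundary conditions: prescribed
#' velocity/k/epsilon profiles at the inlet, no-slip walls, zero reference
#' pressure and zero-gradient outflow at the outlet (axisymmetric mode adds
#' a symmetry axis at y = 0).
#'
#' @param mesh a `structured_mesh`.
#' @param inlet an [inlet_spec()] consistent with the mesh inlet (`nj`
#'   faces).
#' @param fluid a [fluid_properties()] object.
#' @param settings a [solver_settings()] object.
#' @param init optional `flow_field` (or list of field matrices) used as the
#'   initial state; defaults to broadcasting the inlet profile downstream.
#' @return a list with components `flow` (a `flow_field`: cell-centred `u`,
#'   `v`, `p`, `k`, `eps`, `mut` matrices plus face mass fluxes) and
#'   `report` (a `convergence_report`).
#' @export
solve_steady_rans <- function(mesh, inlet, fluid, settings = solver_settings(),
                              init = NULL) {
  stopifnot(inherits(mesh, "structured_mesh"),
            inherits(inlet, "inlet_spec"),
            inherits(fluid, "fluid_properties"),
            inherits(settings, "solver_settings"))
  if (length(inlet$velocity) != mesh$nj)
    stop("inlet profile length does not match the mesh inlet (nj faces)")
  init_list <- NULL
  if (!is.null(init)) {
    f <- if (inherits(init, "flow_field")) init else init
    init_list <- list(u = f$u, v = f$v, p = f$p, k = f$k, eps = f$eps, mut = f$mut)
    if (!all(dim(f$u) == c(mesh$ni, mesh$nj)))
      stop("init fields do not match the mesh dimensions")
  }
  res <- cpp_simple_solve(mesh$xn, mesh$yn,
                          if (mesh$mode == "axisymmetric") 1L else 0L,
                          inlet$velocity, inlet$k, inlet$eps,
                          fluid$rho, fluid$mu, settings_for_cpp(settings),
                          init_list)
  resid <- res$residuals
  colnames(resid) <- c("u", "v", "continuity", "k", "eps")
  if (isTRUE(res$diverged))
    stop(structure(class = c("stenoflow_nonconvergence", "error", "condition"),
                   list(message = sprintf(
                     "solver diverged after %d iterations (momentum residual grew > 1e5-fold)",
                     res$iterations), call = sys.call(),
                     report = list(residuals = resid, converged = FALSE))))
  flow <- structure(list(
    u = res$u, v = res$v, p = res$p, k = res$k, eps = res$eps, mut = res$mut,
    mx = res$mx, my = res$my, mesh = mesh, fluid = fluid,
    inlet = inlet, converged = res$converged,
    mass_imbalance = res$mass_imbalance
  ), class = "flow_field")
  report <- structure(list(
    residuals = resid, converged = res$converged,
    iterations_used = res$iterations,
    n_clipped_k = res$n_clipped_k, n_clipped_eps = res$n_clipped_eps,
    mass_imbalance = res$mass_imbalance,
    tolerance = settings$residual_tolerance
  ), class = "convergence_report")
  if (!res$converged)
    warning(sprintf("solver stopped at max_iterations = %d without reaching %g (final max residual %.3g)",
                    settings$max_iterations, settings$residual_tolerance,
                    max(resid[nrow(resid), ])), call. = FALSE)
  list(flow = flow, report = report)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("RANS flow field on %d x %d cells (%s)\n",
              x$mesh$ni, x$mesh$nj, x$mesh$mode))
  cat(sprintf("  converged: %s; max |U| = %.4g m/s, max k = %.4g m2/s2\n",
              x$converged, max(abs(x$u)), max(x$k)))
  cat(sprintf("  global mass imbalance: %.3g (relative)\n", x$mass_imbalance))
  invisible(x)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report: %s in %d iterations (tolerance %g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations_used, x$tolerance))
  fin <- x$residuals[nrow(x$residuals), ]
  cat("  final residuals:",
      paste(sprintf("%s=%.2e", colnames(x$residuals), fin), collapse = ", "), "\n")
  invisible(x)
}

#' Eddy viscosity of the standard k-epsilon model
#'
#' `mu_t = rho * C_mu * k^2 / eps`, elementwise. `eps` values below
#' `eps_floor` are clamped (and counted in a message) before dividing.
#'
#' @param k turbulent kinetic energy (m^2/s^2), any numeric shape.
#' @param eps dissipation rate (m^2/s^3), same shape as `k`.
#' @param fluid a [fluid_properties()] object.
#' @param c_mu model constant (default 0.09).
#' @param eps_floor clamp floor for `eps` (default 1e-12).
#' @return eddy viscosity in Pa.s, same shape as `k`.
#' @examples
#' compute_eddy_viscosity(1, 1, fluid_properties(1, 1)) # C_mu = 0.09
#' @export
compute_eddy_viscosity <- function(k, eps, fluid, c_mu = KE_CONSTANTS$c_mu,
                                   eps_floor = 1e-12) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(k < 0)) stop("k must be non-negative")
  n_low <- sum(eps < eps_floor)
  if (n_low > 0)
    message(sprintf("compute_eddy_viscosity: clamped %d eps value(s) to the %g floor",
                    n_low, eps_floor))
  fluid$rho * c_mu * k^2 / pmax(eps, eps_floor)
}

#' Assemble one finite-volume transport equation
#'
#' Produces the per-cell five-band linear system (`aP`, `aE`, `aW`, `aN`,
#' `aS`, `b`, convention `aP*phi = aE*phiE + aW*phiW + aN*phiN + aS*phiS +
#' b`) of the discretized equation for `"u"`, `"v"`, `"k"` or `"eps"` about
#' a given flow state: upwinded convection with minmod-limited second-order
#' deferred correction, central diffusion, sources and boundary closures,
#' exactly as used inside the solver iteration.
#'
#' @param field_name `"u"`, `"v"`, `"k"` or `"eps"`.
#' @param mesh a `structured_mesh`.
#' @param flow a `flow_field` or a list with `u`, `v`, `p`, `k`, `eps`,
#'   `mut` matrices describing the current state.
#' @param fluid a [fluid_properties()] object.
#' @param settings a [solver_settings()] object.
#' @param inlet an [inlet_spec()]; defaults to the one stored in `flow`.
#' @return an object of class `fv_system`.
#' @export
assemble_transport_equation <- function(field_name, mesh, flow, fluid,
                                        settings = solver_settings(),
                                        inlet = NULL) {
  stopifnot(inherits(mesh, "structured_mesh"))
  inlet <- inlet %||% flow$inlet
  if (is.null(inlet)) stop("an inlet_spec is required")
  sys <- cpp_assemble(field_name, mesh$xn, mesh$yn,
                      if (mesh$mode == "axisymmetric") 1L else 0L,
                      as_field_matrix(flow$u, mesh), as_field_matrix(flow$v, mesh),
                      as_field_matrix(flow$p, mesh), as_field_matrix(flow$k, mesh),
                      as_field_matrix(flow$eps, mesh), as_field_matrix(flow$mut, mesh),
                      inlet$velocity, inlet$k, inlet$eps,
                      fluid$rho, fluid$mu, settings_for_cpp(settings))
  structure(sys, class = "fv_system", field = field_name)
}

as_field_matrix <- function(x, mesh) {
  if (is.null(x)) x <- 0
  if (length(x) == 1) x <- matrix(x, mesh$ni, mesh$nj)
  stopifnot(all(dim(x) == c(mesh$ni, mesh$nj)))
  x
}

#' Convert an assembled system to an explicit sparse matrix
#'
#' @param system an `fv_system` from [assemble_transport_equation()].
#' @return list with a `Matrix::sparseMatrix` `A` and right-hand side `b`,
#'   cells ordered column-major `(i, j)`.
#' @export
fv_system_matrix <- function(system) {
  stopifnot(inherits(system, "fv_system"))
  ni <- system$ni; nj <- system$nj; n <- ni * nj
  idx <- seq_len(n)
  i0 <- (idx - 1) %% ni
  j0 <- (idx - 1) %/% ni
  rows <- idx; cols <- idx; vals <- system$aP
  add <- function(mask, off, coef) {
    rows <<- c(rows, idx[mask]); cols <<- c(cols, idx[mask] + off)
    vals <<- c(vals, -coef[mask])
  }
  add(i0 < ni - 1, 1L, system$aE)
  add(i0 > 0, -1L, system$aW)
  add(j0 < nj - 1, ni, system$aN)
  add(j0 > 0, -ni, system$aS)
  list(A = Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n)),
       b = system$b)
}

#' Normalized L1 residual of a linear system
#'
#' `|A x - b|_1 / (sum |diag(A) * x| + |b|_1)` — the fixed normalization
#' convention used for the solver's convergence criterion, dimensionless and
#' comparable across equations. If the normalization scale is zero the raw
#' L1 residual is returned (with a message).
#'
#' @param system either an `fv_system` or a list with a square matrix `A`
#'   and right-hand side `b`.
#' @param solution the current iterate `x`.
#' @return normalized residual (scalar).
#' @export
compute_residuals <- function(system, solution) {
  if (inherits(system, "fv_system")) system <- fv_system_matrix(system)
  A <- system$A; b <- system$b
  x <- as.numeric(solution)
  r <- sum(abs(as.numeric(A %*% x) - b))
  scale <- sum(abs(Matrix::diag(A) * x)) + sum(abs(b))
  if (scale == 0) {
    message("compute_residuals: zero normalization scale; returning the raw residual")
    return(r)
  }
  r / scale
}

#' Wall-function relations
#'
#' `wall_uplus` evaluates the dimensionless near-wall velocity: the log-law
#' `u+ = ln(E y+) / kappa` above the sublayer crossover `yplus_lam`, the
#' linear law `u+ = y+` below it. `eps_wall` is the equilibrium dissipation
#' imposed in wall-adjacent cells, `C_mu^(3/4) k^(3/2) / (kappa y)`.
#' `wall_function_coefficients` evaluates the wall treatment for every
#' wall-adjacent cell of a flow state: wall distance, `y*`, wall shear
#' stress and the implicit momentum coefficient.
#'
#' @param yplus dimensionless wall distance.
#' @param kappa von Karman constant (0.41).
#' @param E log-law roughness constant (9.8).
#' @param yplus_lam sublayer/log-layer crossover (11.25).
#' @return `wall_uplus`: u+ values; `eps_wall`: dissipation rate (m^2/s^3).
#' @export
wall_uplus <- function(yplus, kappa = KE_CONSTANTS$kappa, E = KE_CONSTANTS$E_wall,
                       yplus_lam = 11.25) {
  ifelse(yplus > yplus_lam, log(E * yplus) / kappa, yplus)
}

#' @rdname wall_uplus
#' @param k turbulent kinetic energy at the wall-adjacent cell (m^2/s^2).
#' @param y wall-normal distance of the cell centre (m).
#' @param c_mu model constant (0.09).
#' @export
eps_wall <- function(k, y, kappa = KE_CONSTANTS$kappa, c_mu = KE_CONSTANTS$c_mu) {
  if (any(y <= 0)) stop("wall distance must be positive")
  c_mu^0.75 * pmax(k, 0)^1.5 / (kappa * y)
}

#' @rdname wall_uplus
#' @param mesh a `structured_mesh`.
#' @param flow a `flow_field`.
#' @param fluid a [fluid_properties()] object.
#' @export
wall_function_coefficients <- function(mesh, flow, fluid) {
  stopifnot(inherits(mesh, "structured_mesh"), inherits(flow, "flow_field"))
  kap <- KE_CONSTANTS$kappa; E <- KE_CONSTANTS$E_wall; cmu <- KE_CONSTANTS$c_mu
  rows <- list()
  walls <- if (mesh$mode == "planar") c(1L, mesh$nj) else mesh$nj
  wd <- wall_distance(mesh)
  for (jw in walls) {
    for (i in seq_len(mesh$ni)) {
      yp <- wd[i, jw]
      up <- sqrt(flow$u[i, jw]^2 + flow$v[i, jw]^2) # walls are near-horizontal
      kP <- max(flow$k[i, jw], 0)
      ustar <- cmu^0.25 * sqrt(kP)
      ystar <- fluid$rho * ustar * yp / fluid$mu
      if (ystar > 11.25) {
        tau <- fluid$rho * ustar * kap * up / log(E * ystar)
      } else {
        tau <- fluid$mu * up / yp
      }
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = jw, wall_distance = yp, ystar = ystar, u_parallel = up,
        tau_wall = tau, eps_wall = eps_wall(kP, yp, kap, cmu))
    }
  }
  out <- do.call(rbind, rows)
  nb <- sum(out$ystar > 0 & (out$ystar < 1 | out$ystar > 300))
  if (nb > 0)
    message(sprintf("wall_function_coefficients: %d wall cell(s) outside the advisory y* band [1, 300]", nb))
  out
}
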