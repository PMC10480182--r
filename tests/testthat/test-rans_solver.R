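test_that("fluid properties and Reynolds number are consistent", {
  fl <- fluid_properties(1060, 0.0035)
  expect_equal(fl$nu, 0.0035 / 1060, tolerance = 1e-15)
  expect_equal(reynolds_number(fl, 0.66, 0.02), 1060 * 0.66 * 0.02 / 0.0035)
  expect_error(fluid_properties(-1, 1), "positive")
})

test_that("eddy viscosity follows mu_t = rho C_mu k^2 / eps with clamped floor", {
  fl1 <- fluid_properties(1, 1)
  expect_equal(compute_eddy_viscosity(1, 1, fl1), 0.09, tolerance = 1e-15)
  expect_equal(compute_eddy_viscosity(0, 1, fl1), 0)
  # hand-evaluated value at the reference inlet state
  fl <- fluid_properties(1060, 0.0035)
  k <- 0.0016335
  e <- 0.09^0.75 * k^1.5 / 0.0014
  expect_equal(compute_eddy_viscosity(k, e, fl), 1060 * 0.09 * k^2 / e,
               tolerance = 1e-12)
  expect_message(compute_eddy_viscosity(1, 1e-20, fl), "clamped")
  expect_error(compute_eddy_viscosity(-1, 1, fl), "non-negative")
})

test_that("pure-diffusion assembly reduces to the Laplacian stencil", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  st <- constant_state(mesh)
  fl <- fluid_properties(1, 0.01)
  inl <- inlet_spec(rep(0, 10), 0, 1e-3)
  set <- solver_settings(relax_u = 1, relax_p = 1, relax_turb = 1,
                         turbulence = FALSE,
                         convection_scheme = "first-order-upwind")
  sys <- assemble_transport_equation("u", mesh, st, fl, set, inlet = inl)
  dx <- diff(mesh$axial_station)[1]
  dy <- 0.02 / 10
  De <- fl$mu * dy / dx
  Dn <- fl$mu * dx / dy
  id <- function(i, j) i + (j - 1) * mesh$ni
  c0 <- id(6, 5) # interior cell
  expect_equal(sys$aE[c0], De, tolerance = 1e-12)
  expect_equal(sys$aW[c0], De, tolerance = 1e-12)
  expect_equal(sys$aN[c0], Dn, tolerance = 1e-12)
  expect_equal(sys$aS[c0], Dn, tolerance = 1e-12)
  expect_equal(sys$aP[c0], 2 * De + 2 * Dn, tolerance = 1e-12)
  expect_equal(sys$b[c0], 0)
})

test_that("uniform-velocity first-order-upwind coefficients match the closed form", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  U <- 0.3
  st <- constant_state(mesh, u = U)
  fl <- fluid_properties(2, 0.01)
  inl <- inlet_spec(rep(U, 10), 0, 1e-3)
  set <- solver_settings(relax_u = 1, relax_p = 1, relax_turb = 1,
                         turbulence = FALSE,
                         convection_scheme = "first-order-upwind")
  sys <- assemble_transport_equation("u", mesh, st, fl, set, inlet = inl)
  dx <- diff(mesh$axial_station)[1]
  dy <- 0.02 / 10
  De <- fl$mu * dy / dx; Dn <- fl$mu * dx / dy
  Fe <- fl$rho * U * dy
  id <- function(i, j) i + (j - 1) * mesh$ni
  c0 <- id(6, 5)
  expect_equal(sys$aW[c0], De + Fe, tolerance = 1e-12)
  expect_equal(sys$aE[c0], De, tolerance = 1e-12)
  expect_equal(sys$aP[c0],
               sys$aE[c0] + sys$aW[c0] + sys$aN[c0] + sys$aS[c0],
               tolerance = 1e-12) # conservative: aP = sum of neighbours
})

test_that("k-equation production on a linear shear matches mu_t gamma^2 V", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  gam <- 25 # shear rate du/dy
  yc <- (mesh$yn[1, -1] + mesh$yn[1, -11]) / 2
  st <- constant_state(mesh, k = 0.01, eps = 0.5, mut = 0.002)
  st$u <- matrix(rep(gam * yc, each = mesh$ni), mesh$ni, mesh$nj)
  fl <- fluid_properties(1000, 0.001)
  inl <- inlet_spec(gam * yc, 0.01, 1e-3)
  set <- solver_settings(relax_u = 1, relax_p = 1, relax_turb = 1,
                         turbulence = TRUE,
                         convection_scheme = "first-order-upwind")
  sys <- assemble_transport_equation("k", mesh, st, fl, set, inlet = inl)
  dx <- diff(mesh$axial_station)[1]
  dy <- 0.02 / 10
  id <- function(i, j) i + (j - 1) * mesh$ni
  c0 <- id(6, 5) # interior, not wall-adjacent
  expect_equal(sys$b[c0], 0.002 * gam^2 * dx * dy, tolerance = 1e-10)
})

test_that("assembled eps equation imposes the wall dissipation row", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  st <- constant_state(mesh, u = 0.5, k = 0.01, eps = 0.5, mut = 0.002)
  fl <- fluid_properties(1000, 0.001)
  inl <- inlet_spec(rep(0.5, 10), 0.01, 1e-3)
  set <- solver_settings(relax_u = 1, relax_p = 1, relax_turb = 1)
  sys <- assemble_transport_equation("eps", mesh, st, fl, set, inlet = inl)
  id <- function(i, j) i + (j - 1) * mesh$ni
  cw <- id(6, 1) # wall-adjacent cell
  yp <- wall_distance(mesh)[6, 1]
  expect_equal(sys$aP[cw], 1)
  expect_equal(sys$aE[cw] + sys$aW[cw] + sys$aN[cw] + sys$aS[cw], 0)
  expect_equal(sys$b[cw], eps_wall(0.01, yp), tolerance = 1e-12)
})

test_that("normalized residual follows the fixed convention", {
  # exact solution -> 0; zero iterate -> |b|/scale; random system -> direct oracle
  set.seed(11)
  A <- matrix(rnorm(25), 5, 5) + diag(5) * 5
  x <- rnorm(5)
  b <- as.numeric(A %*% x)
  expect_equal(compute_residuals(list(A = A, b = b), x), 0, tolerance = 1e-14)
  expect_equal(compute_residuals(list(A = A, b = b), rep(0, 5)),
               sum(abs(b)) / sum(abs(b)), tolerance = 1e-14)
  x2 <- rnorm(5)
  direct <- sum(abs(A %*% x2 - b)) / (sum(abs(diag(A) * x2)) + sum(abs(b)))
  expect_equal(compute_residuals(list(A = A, b = b), x2), direct,
               tolerance = 1e-14)
  expect_message(compute_residuals(list(A = matrix(0, 2, 2), b = c(0, 0)),
                                   c(0, 0)), "zero normalization")
})

test_that("fv_system converts to a sparse matrix consistent with the bands", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  st <- constant_state(mesh, u = 0.2)
  fl <- fluid_properties(1, 0.01)
  inl <- inlet_spec(rep(0.2, 10), 0, 1e-3)
  set <- solver_settings(relax_u = 1, turbulence = FALSE)
  sys <- assemble_transport_equation("u", mesh, st, fl, set, inlet = inl)
  m <- fv_system_matrix(sys)
  # residual of the flat iterate agrees between band and matrix forms
  x <- rep(0.2, 120)
  expect_equal(compute_residuals(sys, x), compute_residuals(m, x),
               tolerance = 1e-12)
})

test_that("wall-function relations behave across the sublayer crossover", {
  # crossover region: log and linear laws within 5% at y+ = 11
  expect_lt(abs(wall_uplus(11.0) - log(9.8 * 11.0) / 0.41) /
              wall_uplus(11.0), 0.05)
  expect_equal(wall_uplus(5), 5) # sublayer branch
  expect_equal(wall_uplus(100), log(9.8 * 100) / 0.41, tolerance = 1e-12)
  # imposed wall dissipation formula
  expect_equal(eps_wall(0.04, 2e-4), 0.09^0.75 * 0.04^1.5 / (0.41 * 2e-4),
               tolerance = 1e-12)
  expect_error(eps_wall(0.1, -1), "positive")
})

test_that("zero wall-parallel velocity gives zero wall shear", {
  lam <- get_laminar_planar()
  still <- lam$sol$flow
  still$u[] <- 0; still$v[] <- 0; still$k[] <- 0
  wf <- wall_function_coefficients(lam$mesh, still, lam$fluid)
  expect_true(all(wf$tau_wall == 0))
  expect_true(all(wf$wall_distance > 0))
})

test_that("laminar planar duct reproduces plane Poiseuille within 2%", {
  lam <- get_laminar_planar()
  flow <- lam$sol$flow
  expect_true(lam$sol$report$converged)
  i <- which.min(abs(lam$mesh$axial_station - 0.2)) # 10 D downstream
  bulk <- column_bulk_velocity(flow, lam$mesh, i)
  expect_equal(max(flow$u[i, ]) / bulk, 1.5, tolerance = 0.02)
  # mirror symmetry about the centreline
  expect_lt(max(abs(flow$u - flow$u[, 32:1])), 1e-6 * bulk)
})

test_that("laminar axisymmetric pipe reproduces Hagen-Poiseuille within 2%", {
  geo <- build_geometry(0.02, 0, 4, 4, 8)
  mesh <- generate_mesh(geo, ni = 128, nj = 24, wall_stretch_ratio = 1.1,
                        mode = "axisymmetric")
  fl <- fluid_properties(1060, 0.0035)
  U <- 100 * fl$mu / (fl$rho * 0.02)
  sol <- solve_steady_rans(mesh, inlet_spec(rep(U, 24), 0, 1e-3), fl,
                           solver_settings(turbulence = FALSE,
                                           residual_tolerance = 1e-6,
                                           max_iterations = 4000))
  expect_true(sol$report$converged)
  i <- which.min(abs(mesh$axial_station - 0.28))
  bulk <- sum(sol$flow$mx[i, ]) / (fl$rho * sum(inlet_face_areas(mesh)))
  expect_equal(sol$flow$u[i, 1] / bulk, 2.0, tolerance = 0.02)
})

test_that("converged runs conserve mass and keep k, eps admissible", {
  gt <- get_ground_truth()
  expect_true(gt$report$converged)
  expect_lt(gt$flow$mass_imbalance, 1e-6)
  expect_true(all(gt$flow$k >= 0))
  expect_true(all(gt$flow$eps >= 1e-12))
  # eddy-viscosity consistency identity mu_t = rho C_mu k^2 / eps (to the
  # solver's own update relaxation there may be drift; recompute directly)
  mut <- compute_eddy_viscosity(gt$flow$k, gt$flow$eps, fluid_properties())
  expect_lt(median(abs(gt$flow$mut - pmin(mut, 1e5 * 0.0035))) /
              max(gt$flow$mut), 0.02)
  lam <- get_laminar_planar()
  expect_lt(lam$sol$flow$mass_imbalance, 1e-6)
})

test_that("turbulent solution is grid-consistent at the throat under refinement", {
  umax <- sapply(c(1 / 3, 1 / 2), function(sc) {
    gt <- suppressWarnings(run_ground_truth(test_config(scale = sc)))
    max(gt$flow$u)
  })
  expect_lt(abs(umax[2] - umax[1]) / umax[1], 0.02)
})

test_that("repeated solves are bit-identical (deterministic)", {
  cfg <- test_config()
  g1 <- suppressWarnings(run_ground_truth(cfg))
  g2 <- suppressWarnings(run_ground_truth(cfg))
  expect_identical(g1$flow$u, g2$flow$u)
  expect_identical(g1$flow$k, g2$flow$k)
  expect_identical(g1$profiles[["apex"]]$velocity, g2$profiles[["apex"]]$velocity)
})

test_that("solver rejects inconsistent inputs", {
  mesh <- uniform_duct_mesh()
  fl <- fluid_properties()
  expect_error(solve_steady_rans(mesh, inlet_spec(rep(1, 4), 0, 1e-3), fl),
               "does not match")
  expect_error(solver_settings(relax_u = 0), "relaxation")
  expect_error(solver_settings(residual_tolerance = -1), "positive")
})
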