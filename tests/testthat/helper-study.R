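# shared fixtures: all built in code, cached across test files in one session

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# coarse desk-scale study used by the end-to-end tests: 16 cells across the
# diameter keeps every stage well inside interactive runtimes
test_config <- function(...) {
  args <- modifyList(list(scale = 1 / 3, root_seed = 1), list(...))
  do.call(study_config, args)
}

get_ground_truth <- function() {
  cached("gt", suppressWarnings(run_ground_truth(test_config())))
}

get_mapping <- function() {
  cached("mapping", suppressWarnings(
    run_baseline_mapping_verification(test_config(), get_ground_truth())))
}

get_ti_study <- function() {
  cached("ti", suppressWarnings(run_ti_study(test_config(), get_ground_truth())))
}

get_degradation <- function() {
  cached("deg", suppressWarnings(
    run_degradation_study(test_config(), get_ground_truth())))
}

# straight-duct laminar reference solve (planar), shared by solver tests
get_laminar_planar <- function() {
  cached("lam_planar", {
    geo <- build_geometry(0.02, 0, 4, 4, 4) # straight duct, 12D long
    mesh <- generate_mesh(geo, ni = 96, nj = 32, wall_stretch_ratio = 1.1,
                          mode = "planar")
    fl <- fluid_properties(1060, 0.0035)
    U <- 100 * fl$mu / (fl$rho * 0.02) # Re = 100
    inl <- inlet_spec(rep(U, 32), 0, 1e-3)
    sol <- solve_steady_rans(mesh, inl, fl,
                             solver_settings(turbulence = FALSE,
                                             residual_tolerance = 1e-9,
                                             max_iterations = 5000))
    list(mesh = mesh, fluid = fl, U = U, sol = sol)
  })
}

# a tiny uniform mesh + quiescent state for assembly oracles
uniform_duct_mesh <- function(ni = 12, nj = 10, D = 0.02, len_D = 3) {
  geo <- build_geometry(D, 0, len_D / 3, len_D / 3, len_D / 3)
  generate_mesh(geo, ni = ni, nj = nj, wall_stretch_ratio = 1, mode = "planar")
}

constant_state <- function(mesh, u = 0, v = 0, p = 0, k = 0, eps = 1e-12, mut = 0) {
  list(u = matrix(u, mesh$ni, mesh$nj), v = matrix(v, mesh$ni, mesh$nj),
       p = matrix(p, mesh$ni, mesh$nj), k = matrix(k, mesh$ni, mesh$nj),
       eps = matrix(eps, mesh$ni, mesh$nj), mut = matrix(mut, mesh$ni, mesh$nj))
}

# trend acceptance used for the degradation series: at most one adjacent
# inversion, or a Spearman rank trend of the expected sign
trend_holds <- function(x, decreasing = TRUE) {
  inv <- if (decreasing) sum(diff(x) > 0) else sum(diff(x) < 0)
  rho <- suppressWarnings(cor(seq_along(x), x, method = "spearman"))
  inv <= 1 || (!is.na(rho) && (if (decreasing) rho <= 0 else rho >= 0))
}

# bulk velocity at an x-face column from the face mass fluxes
column_bulk_velocity <- function(flow, mesh, i) {
  sum(flow$mx[i, ]) / (flow$fluid$rho * sum(inlet_face_areas(mesh)))
}
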