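test_that("k_from_intensity evaluates (3/2)(UI)^2 and scales quadratically", {
  expect_equal(k_from_intensity(0.66, 0.05), 1.5 * (0.66 * 0.05)^2,
               tolerance = 1e-15)
  expect_equal(k_from_intensity(0.66, 0.05), 0.0016335, tolerance = 1e-12)
  expect_equal(k_from_intensity(10, 0), 0)
  expect_equal(k_from_intensity(1, 1), 1.5)
  # homogeneous of degree 2 in each argument
  for (s in c(0.5, 2, 3.7)) {
    expect_equal(k_from_intensity(s * 0.4, 0.1), s^2 * k_from_intensity(0.4, 0.1))
    expect_equal(k_from_intensity(0.4, s * 0.1), s^2 * k_from_intensity(0.4, 0.1))
  }
  expect_error(k_from_intensity(-1, 0.1), "non-negative")
})

test_that("intensity_from_reynolds follows 0.16 Re^(-1/8), strictly decreasing", {
  expect_equal(intensity_from_reynolds(4000), 0.16 * 4000^(-1 / 8),
               tolerance = 1e-15)
  expect_equal(intensity_from_reynolds(4000), 0.0567, tolerance = 1e-3)
  expect_equal(intensity_from_reynolds(1), 0.16)
  res <- 10^seq(1, 8, length.out = 60)
  vals <- intensity_from_reynolds(res)
  expect_true(all(diff(vals) < 0))
  expect_lt(intensity_from_reynolds(1e9), 0.016)
  expect_error(intensity_from_reynolds(0), "positive")
})

test_that("eps_from_mixing_length follows the mixing-length relation", {
  k <- 0.0016335
  expect_equal(eps_from_mixing_length(k, 0.0014),
               0.09^0.75 * k^1.5 / 0.0014, tolerance = 1e-12)
  expect_equal(eps_from_mixing_length(0, 0.0014), 0)
  # doubling l halves eps
  expect_equal(eps_from_mixing_length(k, 0.0028),
               eps_from_mixing_length(k, 0.0014) / 2, tolerance = 1e-14)
  expect_error(eps_from_mixing_length(k, 0), "positive")
  expect_error(eps_from_mixing_length(-k, 0.001), "non-negative")
})

test_that("inlet_spec validates and derives its dissipation profile", {
  sp <- inlet_spec(rep(0.66, 8), 0.0016335, 0.000375, mode = "uniform_TI",
                   intensity = 0.05)
  expect_equal(sp$k, rep(0.0016335, 8))
  expect_equal(sp$eps, rep(eps_from_mixing_length(0.0016335, 0.000375), 8))
  expect_error(inlet_spec(c(1, NaN), 0, 1e-3), "finite")
  expect_error(inlet_spec(c(1, 1), -0.1, 1e-3), "non-negative")
  expect_error(inlet_spec(c(1, 1), c(0, 0, 0), 1e-3), "equal length")
})

test_that("plane extraction preserves mass flux and sees the jet acceleration", {
  gt <- get_ground_truth()
  ap <- gt$profiles[["apex"]]
  inlet_flux <- 1060 * 0.66 * 0.02
  expect_equal(profile_mass_flux(ap, 1060), inlet_flux,
               tolerance = 1e-8)
  # jet: profile max must exceed the continuity-based mean U * A_in/A_throat * 0.9
  expect_gt(max(ap$velocity), 0.66 * 2 * 0.9)
  # positions strictly increasing across the lumen
  expect_true(all(diff(ap$positions) > 0))
  expect_error(extract_plane_profile(gt$flow, gt$mesh, 0.12345), "grid column")
})

test_that("extraction of a uniform flow returns the constant profile", {
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  fl <- fluid_properties(2, 0.001)
  U <- 0.4
  A <- inlet_face_areas(mesh)
  flow <- structure(list(
    u = matrix(U, 12, 10), v = matrix(0, 12, 10), p = matrix(0, 12, 10),
    k = matrix(0.02, 12, 10), eps = matrix(1, 12, 10), mut = matrix(0, 12, 10),
    mx = matrix(rep(fl$rho * U * A, each = 13), 13, 10),
    my = matrix(0, 12, 11), mesh = mesh, fluid = fl,
    inlet = inlet_spec(rep(U, 10), 0.02, 1e-3), converged = TRUE,
    mass_imbalance = 0), class = "flow_field")
  pr <- extract_plane_profile(flow, mesh, mesh$axial_station[5])
  expect_equal(pr$velocity, rep(U, 10), tolerance = 1e-14)
  expect_equal(pr$k, rep(0.02, 10), tolerance = 1e-14)
})

test_that("node-coincident mapping is exact; resampled mapping interpolates linearly", {
  gt <- get_ground_truth()
  sub <- extract_submodel_mesh(gt$mesh, gt$cuts[[1]])
  ap <- gt$profiles[[1]]
  inl <- map_profile_to_inlet(ap, sub, 0.000375)
  expect_identical(inl$velocity, ap$velocity) # bit-identical on shared nodes
  expect_identical(inl$k, ap$k)
  expect_equal(inl$eps, eps_from_mixing_length(ap$k, 0.000375))

  # synthetic fine profile onto a coarse inlet: hand-computed linear interp
  mesh <- uniform_duct_mesh(ni = 12, nj = 10)
  yc <- (mesh$yn[1, -1] + mesh$yn[1, -11]) / 2
  fine_y <- seq(-0.01, 0.01, length.out = 41)
  prof <- structure(list(positions = fine_y, velocity = 1 + 50 * fine_y,
                         k = 0.01 + abs(fine_y), face_areas = rep(0.02 / 41, 41),
                         lumen = c(-0.01, 0.01), diameter_ref = 0.02,
                         station_label = "x", axial_position = 0.01),
                    class = "plane_profile")
  mapped <- map_profile_to_inlet(prof, mesh, 1e-3)
  manual <- sapply(yc, function(y) {
    i <- max(which(fine_y <= y))
    w <- (y - fine_y[i]) / (fine_y[i + 1] - fine_y[i])
    (1 - w) * (0.01 + abs(fine_y[i])) + w * (0.01 + abs(fine_y[i + 1]))
  })
  expect_equal(mapped$k, manual, tolerance = 1e-12)
  # mapped mass flux preserved by the uniform flux correction
  dy <- diff(mesh$yn[1, ])
  expect_equal(sum(mapped$velocity * dy), sum(prof$velocity * prof$face_areas),
               tolerance = 1e-12)

  # constant profile maps to a constant regardless of resolution
  prof$velocity <- rep(0.7, 41); prof$k <- rep(0.003, 41)
  flat <- map_profile_to_inlet(prof, mesh, 1e-3)
  expect_equal(flat$velocity, rep(0.7, 10), tolerance = 1e-12)
  expect_equal(flat$k, rep(0.003, 10), tolerance = 1e-14)

  # extrapolation beyond the profile lumen is refused
  narrow <- prof
  narrow$positions <- fine_y / 10; narrow$lumen <- c(-0.001, 0.001)
  expect_error(map_profile_to_inlet(narrow, mesh, 1e-3), "extrapolation")
})

test_that("uniform-TI inlets compose k_from_intensity and match mass flux", {
  gt <- get_ground_truth()
  sub <- extract_submodel_mesh(gt$mesh, gt$cuts[[1]])
  sp <- build_uniform_ti_inlet(0.66, 0.05, 0.000375, sub)
  expect_equal(sp$k, rep(0.0016335, sub$nj), tolerance = 1e-12)
  expect_identical(build_uniform_ti_inlet(0.66, 0.05, 0.000375, sub),
                   sp) # determinism
  sp0 <- build_uniform_ti_inlet(0.66, 0, 0.000375, sub)
  expect_equal(sp0$k, rep(0, sub$nj))

  # profile-anchored TI inlet: constant k at (3/2)(Umean I)^2, mapped velocity
  ap <- gt$profiles[[1]]
  ti <- ti_inlet_from_profile(ap, 0.10, 0.000375, sub)
  Umean <- sum(ap$velocity * ap$face_areas) / sum(ap$face_areas)
  expect_equal(unique(ti$k), k_from_intensity(Umean, 0.10), tolerance = 1e-12)
  expect_identical(ti$velocity, ap$velocity)
  # uniform-velocity variant preserves the mass flux exactly
  tiu <- ti_inlet_from_profile(ap, 0.10, 0.000375, sub, uniform_velocity = TRUE)
  expect_equal(sum(tiu$velocity * ap$face_areas),
               sum(ap$velocity * ap$face_areas), tolerance = 1e-12)
})

test_that("round trip: sub-model solved with mapped BCs returns them at its inlet", {
  gt <- get_ground_truth()
  cfg <- test_config()
  sub <- extract_submodel_mesh(gt$mesh, gt$cuts[[3]])
  inl <- map_profile_to_inlet(gt$profiles[[3]], sub, cfg$mixing_length_sub)
  sol <- suppressWarnings(solve_steady_rans(sub, inl, fluid_properties(),
                                            solver_settings()))
  back <- extract_plane_profile(sol$flow, sub, sub$axial_station[1])
  expect_identical(back$velocity, inl$velocity)
  expect_identical(back$k, inl$k)
})

test_that("plane profiles serialize to CSV + JSON and read back", {
  gt <- get_ground_truth()
  path <- tempfile(fileext = ".csv")
  write_plane_profile(gt$profiles[[2]], path)
  back <- read_plane_profile(path)
  expect_equal(back$velocity, gt$profiles[[2]]$velocity, tolerance = 1e-12)
  expect_equal(back$k, gt$profiles[[2]]$k, tolerance = 1e-12)
  expect_equal(back$station_label, "0.5D")
  unlink(c(path, paste0(path, ".json")))
})
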