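test_that("geometry construction honours the severity definition and validates inputs", {
  geo <- build_geometry(0.02, 0.5, 6, 2, 8)
  # throat width = (1 - severity) * D at the apex
  expect_equal(2 * wall_halfwidth(geo, apex_station(geo)), 0.01, tolerance = 1e-14)
  expect_equal(apex_station(geo), 0.14)

  # zero severity: constant width D everywhere
  geo0 <- build_geometry(0.02, 0, 6, 2, 8)
  xs <- seq(0, geo0$total_length, length.out = 101)
  expect_true(all(abs(wall_halfwidth(geo0, xs) - 0.01) < 1e-15))

  # linear scaling of the severity definition
  geo2 <- build_geometry(1.0, 0.75, 6, 2, 8)
  expect_equal(2 * wall_halfwidth(geo2, apex_station(geo2)), 0.25, tolerance = 1e-14)

  expect_error(build_geometry(0.02, 1.0, 6, 2, 8), "degenerate")
  expect_error(build_geometry(0.02, 0.5, -1, 2, 8), "positive")
  expect_error(build_geometry(-0.02, 0.5, 6, 2, 8), "positive")
})

test_that("wall contour is C1-continuous across the stenosis segment", {
  for (prof in c("cosine", "smooth-step")) {
    geo <- build_geometry(0.02, 0.5, 6, 2, 8, throat_profile = prof)
    h <- function(x) wall_halfwidth(geo, x)
    dx <- 1e-7
    for (x0 in c(geo$stenosis_start, apex_station(geo), geo$stenosis_end)) {
      # one-sided slopes agree (derivative continuous, here zero by symmetry)
      sl <- (h(x0 + dx) - h(x0 - dx)) / (2 * dx)
      expect_lt(abs(sl), 1e-3)
      expect_lt(abs(h(x0 + dx) - h(x0)), 1e-8) # value continuous
    }
  }
})

test_that("cut planes sit at apex, apex+0.5D and apex+1.0D", {
  geo <- build_geometry(0.02, 0.5, 6, 2, 8)
  expect_equal(cut_plane(geo, "apex")$axial_position, 0.14)
  expect_equal(cut_plane(geo, "0.5D")$axial_position, 0.15)
  expect_equal(cut_plane(geo, "1.0D")$axial_position, 0.16)
  expect_error(cut_plane(geo, 10), "outside")
})

test_that("uniform straight-duct mesh has equal-area cells", {
  geo <- build_geometry(0.02, 0, 4, 2, 4)
  mesh <- generate_mesh(geo, ni = 10, nj = 10, wall_stretch_ratio = 1)
  areas <- mesh_cell_areas(mesh)
  expect_equal(length(areas), 100)
  expect_lt(diff(range(areas)) / mean(areas), 1e-12)
})

test_that("wall-adjacent cell height follows the geometric-progression closed form", {
  geo <- build_geometry(0.02, 0, 4, 2, 4)
  r <- 1.2; nj <- 16; m <- nj / 2
  mesh <- generate_mesh(geo, ni = 12, nj = nj, wall_stretch_ratio = r)
  # first transverse node gap at the inlet column, against the series formula
  h_half <- 0.01
  expected <- h_half * (r - 1) / (r^m - 1)
  got <- mesh$yn[1, 2] - mesh$yn[1, 1]
  expect_equal(got, expected, tolerance = 1e-12)
  # heights grow by exactly r away from the wall
  gaps <- diff(mesh$yn[1, 1:(m + 1)])
  expect_equal(gaps[-1] / gaps[-m], rep(r, m - 1), tolerance = 1e-10)
})

test_that("stenosed mesh conforms to the wall and clusters at the apex", {
  geo <- build_geometry(0.02, 0.5, 6, 2, 8)
  mesh <- generate_mesh(geo, ni = 72, nj = 16,
                        stations = c(0.12, 0.14, 0.15, 0.16))
  # wall nodes lie exactly on the contour
  expect_equal(mesh$yn[, 17], wall_halfwidth(geo, mesh$axial_station),
               tolerance = 1e-14)
  # transverse extent at the apex column is at most half the inlet extent
  ic <- which(abs(mesh$axial_station - 0.14) < 1e-12)
  apex_dy <- min(diff(mesh$yn[ic, ]))
  inlet_dy <- min(diff(mesh$yn[1, ]))
  expect_lte(apex_dy, inlet_dy / 2 + 1e-15)
  # all cells positive area
  expect_true(all(mesh_cell_areas(mesh) > 0))
  # wall distance strictly positive at every cell centre
  expect_true(all(wall_distance(mesh) > 0))
})

test_that("inlet face areas sum to the channel width / disc area", {
  geo <- build_geometry(0.02, 0.5, 6, 2, 8)
  mp <- generate_mesh(geo, ni = 24, nj = 12, wall_stretch_ratio = 1.2)
  expect_equal(sum(inlet_face_areas(mp)), 0.02, tolerance = 1e-10)
  ma <- generate_mesh(geo, ni = 24, nj = 12, wall_stretch_ratio = 1.2,
                      mode = "axisymmetric")
  expect_equal(2 * pi * sum(inlet_face_areas(ma)), pi * 0.01^2,
               tolerance = 1e-10)
})

test_that("mesh area matches quadrature of the wall contour on refined grids", {
  geo <- build_geometry(0.02, 0.5, 1, 2, 1) # short domain, stenosis-dominated
  analytic <- integrate(function(x) 2 * wall_halfwidth(geo, x),
                        0, geo$total_length, rel.tol = 1e-13)$value
  mesh <- generate_mesh(geo, ni = 8000, nj = 8)
  expect_equal(mesh_total_area(mesh), analytic, tolerance = 1e-8)
  # straight duct: area exact and refinement-invariant
  geo0 <- build_geometry(0.02, 0, 1, 2, 1)
  a1 <- mesh_total_area(generate_mesh(geo0, ni = 16, nj = 8))
  a2 <- mesh_total_area(generate_mesh(geo0, ni = 32, nj = 16))
  expect_equal(a1, 0.02 * geo0$total_length, tolerance = 1e-12)
  expect_lt(abs(a2 - a1) / a1, 1e-10)
})

test_that("sub-model extraction slices exactly at a grid column", {
  geo <- build_geometry(0.02, 0.5, 6, 2, 8)
  mesh <- generate_mesh(geo, ni = 72, nj = 16,
                        stations = c(0.12, 0.14, 0.15, 0.16))
  sub <- extract_submodel_mesh(mesh, cut_plane(geo, "apex"))
  # sub-model inlet coincides with the throat: width = (1-s) D = 0.01 m
  expect_equal(sum(inlet_face_areas(sub)), 0.01, tolerance = 1e-12)
  expect_equal(attr(sub, "cut_offset"), 0.14)
  # inlet nodes coincide with the full-mesh cut column, node for node
  ic <- which(abs(mesh$axial_station - 0.14) < 1e-12)
  expect_identical(sub$yn[1, ], mesh$yn[ic, ])

  # axial extent arithmetic for the 1.0D cut: 16D - 7D - 1D = 8D
  sub3 <- extract_submodel_mesh(mesh, cut_plane(geo, "1.0D"))
  expect_equal(max(sub3$axial_station) - min(sub3$axial_station), 8 * 0.02,
               tolerance = 1e-12)

  # identity cut and idempotence
  sub0 <- extract_submodel_mesh(mesh, 0)
  expect_identical(sub0$xn, mesh$xn)
  again <- extract_submodel_mesh(sub0, 0)
  expect_identical(again$xn, mesh$xn)

  expect_error(extract_submodel_mesh(mesh, geo$total_length + 0.01), "beyond")
  expect_error(extract_submodel_mesh(mesh, 0.1234567), "grid column")
})

test_that("VTK export writes a well-formed structured grid", {
  mesh <- uniform_duct_mesh(ni = 10, nj = 10)
  path <- tempfile(fileext = ".vtk")
  write_vtk(mesh, path, fields = list(dummy = matrix(1, 10, 10)))
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET STRUCTURED_GRID")
  expect_equal(lines[5], "DIMENSIONS 11 11 1")
  expect_true(any(grepl("^CELL_DATA 100$", lines)))
  unlink(path)
})
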