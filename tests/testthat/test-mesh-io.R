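test_that("surface_mesh validates topology and normals", {
  m <- flat_patch_mesh()
  expect_s3_class(m, "surface_mesh")
  expect_equal(sqrt(rowSums(m$normals^2)), rep(1, 4), tolerance = 1e-9)
  # quad-like face (repeated index) and bad index are rejected
  expect_error(surface_mesh(m$vertices, rbind(c(1, 1, 2))),
               "repeated vertex")
  expect_error(surface_mesh(m$vertices, rbind(c(1, 2, 9))), "invalid vertex")
  expect_error(surface_mesh(m$vertices, cbind(m$faces, 1L)),
               "unsupported topology")
})

test_that("STL round trip recovers an icosphere", {
  sph <- make_icosphere(2, radius = 1)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sph, path)
  back <- load_mesh(path)
  expect_equal(nrow(back$faces), 20 * 4^2)
  # STL loses indexing; match vertex sets by nearest neighbour
  expect_equal(nrow(back$vertices), nrow(sph$vertices))
  worst <- max(vapply(seq_len(nrow(sph$vertices)), function(i) {
    min(sqrt(rowSums(sweep(back$vertices, 2, sph$vertices[i, ])^2)))
  }, numeric(1)))
  expect_lt(worst, 1e-5)
})

test_that("PLY round trip preserves topology, coordinates and labels", {
  cs <- default_case()
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cs$mesh, path)
  back <- load_mesh(path)
  expect_identical(back$faces, cs$mesh$faces)
  expect_equal(back$vertices, cs$mesh$vertices, tolerance = 1e-5)
  expect_identical(back$region, cs$mesh$region)
})

test_that("PLY with a quad face is rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y",
               "property double z", "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), path)
  expect_error(load_mesh(path), "unsupported topology")
})

test_that("VTK polydata round trip preserves mesh and point data", {
  m <- flat_patch_mesh(nx = 4, ny = 4,
                       region = rep("nonbleb", 16))
  path <- withr::local_tempfile(fileext = ".vtk")
  blebpoint:::write_vtk_polydata(m, path,
                                 point_data = list(pressure = 1:16 * 1.5))
  back <- blebpoint:::read_vtk_polydata(path)
  expect_identical(back$mesh$faces, m$faces)
  expect_equal(back$mesh$vertices, m$vertices, tolerance = 1e-5)
  expect_identical(back$mesh$region, m$region)
  expect_equal(back$point_data$pressure, 1:16 * 1.5)
})

test_that("field series round trips through both on-disk layouts", {
  sph <- make_icosphere(1, radius = 2) # 42 vertices
  nv <- nrow(sph$vertices)
  nt <- 20L
  times <- seq(0, 1.8, length.out = nt)
  set.seed(5)
  fs <- field_series(times,
                     matrix(rnorm(nv * nt, 1000, 10), nv, nt),
                     array(rnorm(nv * 3 * nt), c(nv, 3, nt)),
                     period_T = 1.8)
  dir_csv <- withr::local_tempdir()
  write_field_series(fs, dir_csv)
  back <- load_field_series(dir_csv, sph)
  expect_equal(back$times, fs$times)
  expect_equal(back$pressure, fs$pressure, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$wss, fs$wss, tolerance = 1e-6, ignore_attr = TRUE)

  dir_vtk <- withr::local_tempdir()
  write_vtk_series(fs, sph, dir_vtk)
  back2 <- load_vtk_series(dir_vtk, sph)
  expect_equal(back2$pressure, fs$pressure, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back2$wss, fs$wss, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("field alignment and time-ordering contracts are enforced", {
  nv <- 10
  times <- c(0, 0.5, 1)
  p <- matrix(1, nv, 3)
  w <- array(0, c(nv, 3, 3))
  expect_s3_class(field_series(times, p, w, 1.8), "field_series")
  expect_error(field_series(c(0, 0.5, 0.5), p, w, 1.8), "ordering error")
  expect_error(field_series(times, p[, 1:2], w, 1.8), "alignment error")
  expect_error(field_series(times, p, w[, , 1:2], 1.8), "alignment error")
  # loader catches a vertex-count mismatch against the mesh
  sph <- make_icosphere(1) # 42 vertices
  fs <- field_series(times, p, w, 1.8)
  d <- withr::local_tempdir()
  write_field_series(fs, d)
  expect_error(load_field_series(d, sph), "alignment error")
})

test_that("region label sidecar CSV round trips", {
  cs <- default_case()
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_labels(cs$mesh, path)
  bare <- surface_mesh(cs$mesh$vertices, cs$mesh$faces)
  back <- read_region_labels(bare, path)
  expect_identical(back$region, cs$mesh$region)
})

test_that("inlet plane selects the tube ring and rejects degenerate cases", {
  cs <- default_case()
  inl <- define_inlet_plane(cs$mesh, cs$truth$inlet$origin,
                            cs$truth$inlet$normal, cs$truth$inlet$thickness)
  # members form one circumferential ring of the tube grid
  expect_equal(length(inl$member_vertices), cs$spec$tube_ntheta)
  expect_true(all(abs(cs$mesh$vertices[inl$member_vertices, 1] -
                        cs$truth$inlet$origin[1]) <= 0.125 + 1e-12))
  expect_error(define_inlet_plane(cs$mesh, c(100, 0, 0), c(1, 0, 0), 0.5),
               "empty inlet")
  expect_error(define_inlet_plane(cs$mesh, c(-2.7001, 0, 0), c(1, 0, 0), 0),
               "empty inlet")
})

test_that("inlet membership is invariant under rigid transformation", {
  cs <- default_case()
  inl <- define_inlet_plane(cs$mesh, cs$truth$inlet$origin,
                            cs$truth$inlet$normal, cs$truth$inlet$thickness)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(3, -2, 5)
  mesh2 <- transform_mesh(cs$mesh, R, tr)
  inl2 <- define_inlet_plane(mesh2,
                             as.numeric(R %*% cs$truth$inlet$origin) + tr,
                             as.numeric(R %*% cs$truth$inlet$normal),
                             cs$truth$inlet$thickness)
  expect_identical(inl2$member_vertices, inl$member_vertices)
})
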