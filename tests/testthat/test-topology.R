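test_that("tangential projection removes exactly the normal component", {
  cs <- default_case()
  mesh <- cs$mesh
  # pure normal field projects to zero
  expect_lt(max(abs(tangential_projection(mesh, mesh$normals))), 1e-12)
  # idempotence on an already-tangential field
  set.seed(31)
  f <- matrix(rnorm(3 * nrow(mesh$vertices)), ncol = 3)
  ft <- tangential_projection(mesh, f)
  expect_equal(tangential_projection(mesh, ft), ft, tolerance = 1e-9)
  # orthogonality to the normals
  expect_lt(max(abs(rowSums(ft * mesh$normals))), 1e-9)
})

test_that("surface divergence is exact for constant and linear planar fields", {
  patch <- flat_patch_mesh(10, 10, nx = 11, ny = 11)
  interior <- grid_interior(patch)
  nv <- nrow(patch$vertices)
  # constant field: zero divergence at interior vertices
  dv0 <- surface_divergence(patch, matrix(rep(c(2, -1, 0), each = nv),
                                          ncol = 3))
  expect_lt(max(abs(dv0[interior])), 1e-9)
  # radial field F = (x, y, 0): divergence 2 everywhere (linear, so exact)
  dv2 <- surface_divergence(patch, cbind(patch$vertices[, 1],
                                         patch$vertices[, 2], 0))
  expect_equal(dv2[interior], rep(2, length(interior)), tolerance = 1e-9)
})

test_that("divergence integrates to zero over a closed surface", {
  sph <- make_icosphere(3, radius = 1.75)
  nv <- nrow(sph$vertices)
  f <- tangential_projection(sph, matrix(rep(c(1, 0.3, -0.2), each = nv),
                                         ncol = 3))
  dv <- surface_divergence(sph, f)
  va <- vertex_areas(sph)
  total <- sum(dv * va)
  scale <- sum(abs(dv) * va)
  expect_lt(abs(total) / scale, 1e-6) # discrete divergence theorem
})

test_that("divergence peaks at the planted source", {
  cs <- default_case()
  fs <- make_fields(cs$mesh, cs$truth, seed = 2)
  k <- which.min(abs(fs$times - 2.16))
  tang <- tangential_projection(cs$mesh, fs$wss[, , k])
  dv <- surface_divergence(cs$mesh, tang)
  dome <- cs$truth$dome_vertices
  # the maximum-divergence dome vertex sits within two edges of a source
  top <- dome[which.max(dv[dome])]
  d_top <- min(sqrt(rowSums(sweep(cs$truth$source_locations, 2,
                                  cs$mesh$vertices[top, ], "-")^2)))
  expect_lt(d_top, 0.6)
  # and each source's nearest vertex is in the top divergence percentile
  thr <- stats::quantile(dv[dome], 0.95, na.rm = TRUE)
  for (nm in rownames(cs$truth$source_locations)) {
    src <- cs$truth$source_locations[nm, ]
    d <- sqrt(rowSums(sweep(cs$mesh$vertices, 2, src)^2))
    expect_gt(dv[which.min(d)], thr)
  }
})

test_that("center detection finds planted sources and nothing in uniform flow", {
  patch <- flat_patch_mesh(10, 10, nx = 21, ny = 21)
  nv <- nrow(patch$vertices)
  uni <- matrix(rep(c(1, 0.5, 0), each = nv), ncol = 3)
  dv <- surface_divergence(patch, uni)
  expect_equal(nrow(find_divergence_centers(patch, uni, dv)), 0L)

  cs <- default_case()
  for (seed in c(2, 5, 9)) {
    fs <- make_fields(cs$mesh, cs$truth, seed = seed)
    k <- which.min(abs(fs$times - 2.16))
    tang <- tangential_projection(cs$mesh, fs$wss[, , k])
    dv <- surface_divergence(cs$mesh, tang)
    cen <- find_divergence_centers(cs$mesh, tang, dv,
                                   domain_label = c("bleb", "nonbleb"))
    expect_equal(nrow(cen), 2L)
    expect_setequal(cen$region, c("bleb", "nonbleb"))
    for (nm in rownames(cs$truth$source_locations)) {
      src <- cs$truth$source_locations[nm, ]
      d <- min(sqrt((cen$x - src[1])^2 + (cen$y - src[2])^2 +
                      (cen$z - src[3])^2))
      expect_lte(d, 2 * 0.5) # within twice the sampling spacing
    }
    # detection count is invariant under uniform field scaling
    cen10 <- find_divergence_centers(cs$mesh, 10 * tang, 10 * dv,
                                     domain_label = c("bleb", "nonbleb"))
    expect_identical(cen10$vertex_id, cen$vertex_id)
  }
})

test_that("centers are separated by at least the minimum distance", {
  cs <- default_case()
  fs <- make_fields(cs$mesh, cs$truth, seed = 6)
  k <- which.min(abs(fs$times - 2.16))
  tang <- tangential_projection(cs$mesh, fs$wss[, , k])
  dv <- surface_divergence(cs$mesh, tang)
  cen <- find_divergence_centers(cs$mesh, tang, dv,
                                 domain_label = c("bleb", "nonbleb"),
                                 min_divergence_percentile = 50,
                                 min_separation_mm = 2.5)
  if (nrow(cen) >= 2) {
    dmat <- as.matrix(stats::dist(cen[, c("x", "y", "z")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), 2.5)
  }
  # sorted by descending divergence
  expect_false(is.unsorted(rev(cen$divergence)))
})

test_that("center flags land on the nearest sample point, one per center", {
  pts <- structure(list(
    points = rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)),
    face = c(1L, 1L, 1L), bary = matrix(1 / 3, 3, 3),
    region = c("bleb", "nonbleb", "nonbleb"), records = NULL,
    spacing = 0.5, seed = 1), class = "sample_point_set")
  none <- flag_center_points(pts, blebpoint:::empty_centers())
  expect_false(any(none$records$is_center))
  cen <- data.frame(center_id = 1L, vertex_id = 1L,
                    x = 0.5, y = 0, z = 0, divergence = 5,
                    region = "bleb")
  # equidistant between points 1 and 2: lower point id wins
  flagged <- flag_center_points(pts, cen)
  expect_identical(which(flagged$records$is_center), 1L)
  # two centers nearest to the same point is an assignment error
  cen2 <- rbind(cen, transform(cen, center_id = 2L, x = 0.4))
  expect_error(flag_center_points(pts, cen2), "assignment error")
})
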