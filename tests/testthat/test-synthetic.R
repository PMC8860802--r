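test_that("dome geometry matches the spherical-cap formulas", {
  cs <- default_case()
  mesh <- cs$mesh
  spec <- cs$spec
  dome_faces <- apply(matrix(mesh$region[mesh$faces], ncol = 3) != "vessel",
                      1, all)
  dome_area <- sum(face_areas(mesh)[dome_faces])
  cap_area <- 2 * pi * spec$dome_radius_mm^2 *
    (1 - cos(spec$neck_half_angle_deg * pi / 180))
  expect_lt(abs(dome_area - cap_area) / cap_area, 0.05)
  # labelled bleb area fraction tracks the patch/cap area ratio
  va <- vertex_areas(mesh)
  bleb_frac <- sum(va[mesh$region == "bleb"]) /
    sum(va[mesh$region != "vessel"])
  ang <- spec$bleb_geodesic_radius_mm / spec$dome_radius_mm
  want <- (1 - cos(ang)) / (1 - cos(spec$neck_half_angle_deg * pi / 180))
  expect_lt(abs(bleb_frac - want) / want, 0.10)
})

test_that("generator is deterministic given spec and seed", {
  spec <- synthetic_spec()
  g1 <- make_dome_mesh(spec)
  g2 <- make_dome_mesh(spec)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$mesh$faces, g2$mesh$faces)
  f1 <- make_fields(g1$mesh, g1$truth, seed = 9)
  f2 <- make_fields(g2$mesh, g2$truth, seed = 9)
  expect_identical(f1$pressure, f2$pressure)
  expect_identical(f1$wss, f2$wss)
  n1 <- make_null_fields(g1$mesh, g1$truth, seed = 9)
  n2 <- make_null_fields(g1$mesh, g1$truth, seed = 9)
  expect_identical(n1$pressure, n2$pressure)
  # and the generator does not disturb the session RNG
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_fields(g1$mesh, g1$truth, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("a mesh too coarse for the bleb patch is rejected", {
  expect_error(make_dome_mesh(synthetic_spec(subdivisions = 0L)),
               "resolution error")
})

test_that("OSI is zero without an oscillatory component and rises with it", {
  spec0 <- synthetic_spec(osc_amplitude_pa = 0, pressure_noise_sd_pa = 0,
                          wss_noise_sd_pa = 0)
  gen <- make_dome_mesh(spec0)
  fs0 <- make_fields(gen$mesh, gen$truth)
  inl <- define_inlet_plane(gen$mesh, gen$truth$inlet$origin,
                            gen$truth$inlet$normal,
                            gen$truth$inlet$thickness)
  snap <- select_peak_systole(synthetic_waveform(spec0), 2,
                              spec0$period_T_s)
  idx0 <- compute_index_fields(gen$mesh, fs0, inl, snap)
  expect_lt(max(idx0$osi, na.rm = TRUE), 1e-9) # unidirectional modulation
  # with the oscillatory component the patch center gains OSI
  patch_vertex <- which.min(sqrt(rowSums(
    sweep(gen$mesh$vertices, 2, gen$truth$patch_center)^2)))
  for (amp in c(1, 2, 4)) {
    spec1 <- synthetic_spec(osc_amplitude_pa = amp,
                            pressure_noise_sd_pa = 0, wss_noise_sd_pa = 0)
    g1 <- make_dome_mesh(spec1)
    fs1 <- make_fields(g1$mesh, g1$truth)
    o <- osi(t(fs1$wss[patch_vertex, , ]), fs1$times, spec1$period_T_s)
    if (amp == 1) o_prev <- -1
    expect_gt(o, o_prev)
    expect_lte(o, 0.5)
    o_prev <- o
  }
})

test_that("the pressure patch hits the target maximum normalized pressure", {
  cs <- default_case()
  fs <- make_fields(cs$mesh, cs$truth, seed = 3)
  inl <- define_inlet_plane(cs$mesh, cs$truth$inlet$origin,
                            cs$truth$inlet$normal, cs$truth$inlet$thickness)
  snap <- select_peak_systole(synthetic_waveform(cs$spec), 2,
                              cs$spec$period_T_s)
  idx <- compute_index_fields(cs$mesh, fs, inl, snap)
  dome_max <- max(idx$normalized_pressure[cs$truth$dome_vertices])
  expect_equal(dome_max, cs$spec$target_max_normalized_pressure,
               tolerance = 0.005)
})

test_that("doubling the planted pressure effect widens the group gap", {
  gap_for <- function(target) {
    spec <- synthetic_spec(target_max_normalized_pressure = target)
    gen <- make_dome_mesh(spec)
    fs <- make_fields(gen$mesh, gen$truth, seed = 5)
    inl <- define_inlet_plane(gen$mesh, gen$truth$inlet$origin,
                              gen$truth$inlet$normal,
                              gen$truth$inlet$thickness)
    snap <- select_peak_systole(synthetic_waveform(spec), 2,
                                spec$period_T_s)
    idx <- compute_index_fields(gen$mesh, fs, inl, snap)
    np <- idx$normalized_pressure
    mean(np[gen$mesh$region == "bleb"]) -
      mean(np[gen$mesh$region == "nonbleb"])
  }
  expect_gt(gap_for(1.08), gap_for(1.04))
})

test_that("null fields carry no region effect", {
  cs <- default_case()
  inl <- define_inlet_plane(cs$mesh, cs$truth$inlet$origin,
                            cs$truth$inlet$normal, cs$truth$inlet$thickness)
  snap <- select_peak_systole(synthetic_waveform(cs$spec), 2,
                              cs$spec$period_T_s)
  bleb <- cs$mesh$region == "bleb"
  nonbleb <- cs$mesh$region == "nonbleb"
  within_2se <- logical(50)
  for (s in 1:50) {
    fs <- make_null_fields(cs$mesh, cs$truth, seed = s)
    idx <- compute_index_fields(cs$mesh, fs, inl, snap)
    np <- idx$normalized_pressure
    diff <- mean(np[bleb]) - mean(np[nonbleb])
    se <- sqrt(var(np[bleb]) / sum(bleb) + var(np[nonbleb]) / sum(nonbleb))
    within_2se[s] <- abs(diff) < 2 * se
  }
  expect_gte(mean(within_2se), 0.90)
})

test_that("null replicates rarely produce a significant Fisher test", {
  cal <- null_calibration(200)
  expect_lt(mean(cal$fisher_p < 0.05), 0.10)
})
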