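#' Specification for the synthetic aneurysm test case
#'
#' Defines the dome-on-tube geometry and the planted hemodynamic structure
#' used to exercise the whole pipeline without CFD software. The defaults
#' mirror the scale of the study's Case 1: a 3.5-mm-diameter sac sampled at
#' 0.5-mm spacing (~120 points), a high-pressure patch over the bleb region
#' scaled to a maximum normalized pressure of 1.04, a low-WSS patch, one
#' planted radial WSS source per region, an oscillatory WSS component
#' inside the bleb patch, and a positive two-harmonic inlet waveform of
#' period 1.80 s.
#'
#' @param dome_radius_mm sac radius (default 1.75, a 3.5 mm diameter).
#' @param neck_half_angle_deg polar angle at which the sac is cut off
#'   (default 135: a beyond-hemisphere sac with a narrowed neck).
#' @param tube_radius_mm,tube_length_mm parent-vessel tube geometry.
#' @param subdivisions icosphere subdivision level for the sac (default 3,
#'   ~0.23 mm edges).
#' @param tube_nx,tube_ntheta tube grid resolution (axial rings x
#'   circumferential segments).
#' @param bleb_polar_deg,bleb_azimuth_deg direction of the bleb-patch
#'   center on the sac.
#' @param bleb_geodesic_radius_mm geodesic radius of the labelled bleb
#'   patch (default 0.9, ~8% of the sac area, the order of the study's
#'   bleb-point fraction).
#' @param base_pressure_pa,pressure_gradient_pa_per_mm uniform pressure
#'   level at the inlet and the axial drop downstream.
#' @param pressure_sigma_mm width of the Gaussian high-pressure patch.
#' @param target_max_normalized_pressure dome maximum pressure divided by
#'   the inlet average (default 1.04 as reported for Case 1).
#' @param tau_dome_pa,tau_tube_pa base WSS magnitudes on sac and tube.
#' @param low_wss_factor residual WSS fraction at the bleb-patch center.
#' @param low_wss_sigma_mm width of the low-WSS patch.
#' @param source_strength_pa,source_sigma_mm planted radial WSS-source
#'   amplitude and width.
#' @param source_base_attenuation how strongly the base flow is suppressed
#'   at a planted source (1 = fully: the source is a true stagnation-like
#'   divergence center of the total field).
#' @param source_attenuation_sigma_mm width of the base-flow suppression
#'   window around each source (wider than the source itself so the
#'   radial pattern dominates its neighbourhood).
#' @param nonbleb_source_polar_deg,nonbleb_source_azimuth_deg direction of
#'   the second (non-bleb) planted source.
#' @param osc_amplitude_pa,osc_sigma_mm oscillatory WSS component inside
#'   the bleb patch (zero-mean over the cycle; raises OSI locally).
#' @param period_T_s cardiac period (default 1.80).
#' @param waveform_a1,waveform_a2,peak_time_s two-harmonic waveform shape
#'   and the within-cycle peak-systole time.
#' @param n_steps field time steps over the analysed (second) cycle.
#' @param pressure_noise_sd_pa,wss_noise_sd_pa Gaussian measurement noise.
#' @param seed integer seed; together with the spec it fully determines
#'   the generated fields.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dome_radius_mm = 1.75,
                           neck_half_angle_deg = 135,
                           tube_radius_mm = 1.5,
                           tube_length_mm = 8,
                           subdivisions = 3L,
                           tube_nx = 33L,
                           tube_ntheta = 24L,
                           bleb_polar_deg = 50,
                           bleb_azimuth_deg = 0,
                           bleb_geodesic_radius_mm = 0.9,
                           base_pressure_pa = 1500,
                           pressure_gradient_pa_per_mm = 2,
                           pressure_sigma_mm = 1.0,
                           target_max_normalized_pressure = 1.04,
                           tau_dome_pa = 6,
                           tau_tube_pa = 7,
                           low_wss_factor = 0.3,
                           low_wss_sigma_mm = 0.9,
                           source_strength_pa = 3,
                           source_sigma_mm = 0.5,
                           source_base_attenuation = 1.0,
                           source_attenuation_sigma_mm = 0.8,
                           nonbleb_source_polar_deg = 50,
                           nonbleb_source_azimuth_deg = 180,
                           osc_amplitude_pa = 2,
                           osc_sigma_mm = 0.9,
                           period_T_s = 1.8,
                           waveform_a1 = 0.5,
                           waveform_a2 = 0.2,
                           peak_time_s = 0.36,
                           n_steps = 21L,
                           pressure_noise_sd_pa = 1,
                           wss_noise_sd_pa = 0.05,
                           seed = 1L) {
  spec <- as.list(environment())
  stopifnot(dome_radius_mm > 0, tube_radius_mm > 0, tube_length_mm > 0,
            bleb_geodesic_radius_mm > 0, pressure_sigma_mm > 0,
            tau_dome_pa > 0, tau_tube_pa > 0, period_T_s > 0,
            target_max_normalized_pressure > 1)
  class(spec) <- "synthetic_spec"
  spec
}

unit_direction <- function(polar_deg, azimuth_deg) {
  th <- polar_deg * pi / 180
  ph <- azimuth_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Subdivided icosahedral sphere mesh
#'
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @param radius sphere radius in mm.
#' @return a [surface_mesh()] with `20 * 4^subdivisions` faces.
#' @export
make_icosphere <- function(subdivisions = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_cache[[key]]
      if (!is.null(m)) return(m)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      m <- nrow(verts)
      mid_cache[[key]] <- m
      m
    }
    nf <- matrix(NA_integer_, 4L * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  surface_mesh(v * radius, f)
}

#' Build the synthetic dome-on-tube surface mesh
#'
#' The aneurysm sac is a spherical cap (icosphere cut at
#' `neck_half_angle_deg`) whose opening faces the parent tube below; the
#' tube is an open cylinder along the x axis. Sac vertices within the bleb
#' patch are labelled `bleb`, the rest of the sac `nonbleb`, and the tube
#' `vessel`. Geometry is fully determined by the spec (no randomness).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `mesh` (a [surface_mesh()]) and `truth`: bleb vertex
#'   indices, the 3D bleb-patch center, the two planted-source locations
#'   (rows `bleb`, `nonbleb`), the inlet-plane definition and the spec.
#' @export
make_dome_mesh <- function(spec) {
  r <- spec$dome_radius_mm
  edge <- 1.323 * r / 2^spec$subdivisions # icosphere edge length estimate
  if (edge > spec$bleb_geodesic_radius_mm) {
    stop("resolution error: mesh edge length exceeds the bleb patch radius")
  }
  sph <- make_icosphere(spec$subdivisions, radius = 1)
  zcut <- cos(spec$neck_half_angle_deg * pi / 180)
  keep_v <- sph$vertices[, 3] >= zcut - 1e-9
  keep_f <- keep_v[sph$faces[, 1]] & keep_v[sph$faces[, 2]] &
    keep_v[sph$faces[, 3]]
  old_idx <- which(keep_v)
  remap <- integer(nrow(sph$vertices))
  remap[old_idx] <- seq_along(old_idx)
  dome_v <- sph$vertices[old_idx, , drop = FALSE] * r
  dome_f <- matrix(remap[sph$faces[keep_f, ]], ncol = 3)

  # bleb labels from geodesic (great-circle) distance to the patch center
  bdir <- unit_direction(spec$bleb_polar_deg, spec$bleb_azimuth_deg)
  ang <- acos(pmin(pmax((dome_v / r) %*% bdir, -1), 1))
  dome_region <- ifelse(ang * r <= spec$bleb_geodesic_radius_mm,
                        "bleb", "nonbleb")

  # parent tube: open cylinder along x, top surface touching the sac rim
  rim_z <- zcut * r
  z_axis <- rim_z - spec$tube_radius_mm
  nx <- spec$tube_nx
  nt <- spec$tube_ntheta
  xs <- seq(-spec$tube_length_mm / 2, spec$tube_length_mm / 2,
            length.out = nx)
  th <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  tube_v <- cbind(rep(xs, each = nt),
                  spec$tube_radius_mm * sin(rep(th, nx)),
                  z_axis + spec$tube_radius_mm * cos(rep(th, nx)))
  tube_f <- matrix(NA_integer_, 2L * (nx - 1L) * nt, 3)
  row <- 1L
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(nt)) {
      jn <- if (j == nt) 1L else j + 1L
      a <- (i - 1L) * nt + j
      b <- (i - 1L) * nt + jn
      c2 <- i * nt + j
      d <- i * nt + jn
      tube_f[row, ] <- c(a, c2, b); row <- row + 1L
      tube_f[row, ] <- c(b, c2, d); row <- row + 1L
    }
  }

  vertices <- rbind(dome_v, tube_v)
  faces <- rbind(dome_f, tube_f + nrow(dome_v))
  region <- c(dome_region, rep("vessel", nrow(tube_v)))
  mesh <- surface_mesh(vertices, faces, region = region)

  inlet_x <- -(r + 1) # 1 mm proximal to the sac's upstream extent
  truth <- list(
    bleb_vertices = which(region == "bleb"),
    patch_center = bdir * r,
    source_locations = rbind(
      bleb = bdir * r,
      nonbleb = unit_direction(spec$nonbleb_source_polar_deg,
                               spec$nonbleb_source_azimuth_deg) * r),
    inlet = list(origin = c(inlet_x, 0, z_axis), normal = c(1, 0, 0),
                 thickness = 0.25),
    dome_vertices = which(region != "vessel"),
    spec = spec)
  list(mesh = mesh, truth = truth)
}

#' Synthetic inlet flow waveform
#'
#' A positive two-harmonic pulse of period `period_T_s` covering two
#' cycles, peaking at `peak_time_s` within each cycle:
#' `w(t) = 1 + a1 cos(2 pi (t - tp)/T) + a2 cos(4 pi (t - tp)/T)`.
#'
#' @param spec a [synthetic_spec()].
#' @param dt sample interval in s.
#' @return data.frame with columns `time`, `flow`.
#' @export
synthetic_waveform <- function(spec, dt = 0.02) {
  tt <- seq(0, 2 * spec$period_T_s, by = dt)
  data.frame(time = tt, flow = waveform_value(tt, spec))
}

waveform_value <- function(t, spec) {
  tp <- spec$peak_time_s
  T <- spec$period_T_s
  1 + spec$waveform_a1 * cos(2 * pi * (t - tp) / T) +
    spec$waveform_a2 * cos(4 * pi * (t - tp) / T)
}

# Static (per-vertex) building blocks shared by make_fields and
# make_null_fields: a smooth unit tangential base-flow direction that
# vanishes nowhere on the sac, a unit orthogonal direction for the
# oscillatory component, and distances to the bleb patch.
#
# On the sac (a spherical cap, topologically a disk) a nowhere-zero
# tangent direction exists; we take the pushforward of a constant planar
# field under the inverse stereographic map from the excluded pole, whose
# normalization is therefore smooth and free of direction defects (a
# uniform-magnitude field built by naive projection would necessarily
# carry defects with spurious strong divergence). On the tube the base
# direction is axial.
synthetic_static_parts <- function(mesh, truth) {
  spec <- truth$spec
  v <- mesh$vertices
  nrm <- mesh$normals
  nv <- nrow(v)
  dome <- truth$dome_vertices
  base_dir <- matrix(rep(c(1, 0, 0), each = nv), nv, 3) # tube: axial
  nd <- v[dome, , drop = FALSE] / spec$dome_radius_mm   # unit sphere coords
  u1 <- nd[, 1] / (1 + nd[, 3])
  u2 <- nd[, 2] / (1 + nd[, 3])
  tvec <- cbind(1 + u2^2 - u1^2, -2 * u1 * u2, -2 * u1)
  base_dir[dome, ] <- tvec
  base_dir <- tangential_projection(mesh, base_dir)
  len <- sqrt(rowSums(base_dir^2))
  len[len < 1e-12] <- 1
  base_dir <- base_dir / len
  ortho_dir <- row_cross(nrm, base_dir)
  d_patch <- sqrt(rowSums(sweep(v, 2, truth$patch_center)^2))
  list(spec = spec, base_dir = base_dir, ortho_dir = ortho_dir,
       dome = dome, d_patch = d_patch)
}

#' Generate the planted hemodynamic field series
#'
#' Builds the time-resolved pressure and WSS fields of the default study
#' conditions: a Gaussian high-pressure patch over the bleb region scaled
#' so the dome maximum divided by the inlet average equals the spec's
#' target; a base tangential WSS field attenuated inside the low-WSS patch
#' and around the planted sources; one radially divergent WSS source per
#' region; an orthogonal oscillatory component inside the bleb patch; all
#' modulated by the inlet waveform and covering the second cardiac cycle,
#' plus Gaussian noise. Bit-reproducible for a fixed `(spec, seed)`.
#'
#' @param mesh,truth output of [make_dome_mesh()].
#' @param seed RNG seed (defaults to the spec's).
#' @return a [field_series()] over the second cycle.
#' @export
make_fields <- function(mesh, truth, seed = truth$spec$seed) {
  spec <- truth$spec
  parts <- synthetic_static_parts(mesh, truth)
  v <- mesh$vertices
  nv <- nrow(v)
  dome <- parts$dome

  src <- truth$source_locations
  if (any(!rownames(src) %in% c("bleb", "nonbleb"))) {
    stop("placement error: planted sources must lie on the dome")
  }
  for (s in seq_len(nrow(src))) {
    d_to_dome <- min(sqrt(rowSums(sweep(v[dome, , drop = FALSE], 2,
                                        src[s, ])^2)))
    if (d_to_dome > spec$dome_radius_mm / 2) {
      stop("placement error: planted source lies off the dome surface")
    }
  }

  # pressure profile: axial drop + bleb-patch bump scaled to the target
  inlet <- define_inlet_plane(mesh, truth$inlet$origin, truth$inlet$normal,
                              truth$inlet$thickness)
  p_base <- spec$base_pressure_pa -
    spec$pressure_gradient_pa_per_mm * (v[, 1] - truth$inlet$origin[1])
  p_ref <- inlet_average(mesh, inlet, p_base)
  g <- exp(-parts$d_patch^2 / (2 * spec$pressure_sigma_mm^2))
  target_p <- spec$target_max_normalized_pressure * p_ref
  cand <- dome[g[dome] > 1e-6]
  amp <- min((target_p - p_base[cand]) / g[cand])
  if (amp <= 0) stop("pressure target unattainable with the base profile")
  p_profile <- p_base
  p_profile[dome] <- p_base[dome] + amp * g[dome]

  # WSS magnitude profile (scales the unit base-flow direction)
  mag <- ifelse(seq_len(nv) %in% dome, spec$tau_dome_pa, spec$tau_tube_pa)
  low <- exp(-parts$d_patch^2 / (2 * spec$low_wss_sigma_mm^2))
  mag[dome] <- mag[dome] * (1 - (1 - spec$low_wss_factor) * low[dome])
  f_static <- parts$base_dir * mag
  for (s in seq_len(nrow(src))) {
    d_s <- sqrt(rowSums(sweep(v, 2, src[s, ])^2))
    att <- exp(-d_s^2 / (2 * spec$source_attenuation_sigma_mm^2))
    f_static <- f_static * (1 - spec$source_base_attenuation * att)
    gs <- exp(-d_s^2 / (2 * spec$source_sigma_mm^2))
    away <- tangential_projection(mesh, sweep(v, 2, src[s, ]))
    alen <- sqrt(rowSums(away^2))
    ok <- alen > 1e-9
    away[ok, ] <- away[ok, ] / alen[ok]
    away[!ok, ] <- 0
    f_static <- f_static + spec$source_strength_pa * gs * away
  }
  osc_static <- parts$ortho_dir * spec$osc_amplitude_pa *
    exp(-parts$d_patch^2 / (2 * spec$osc_sigma_mm^2))
  osc_static[-dome, ] <- 0

  T <- spec$period_T_s
  times <- T + seq(0, T, length.out = spec$n_steps)
  w <- waveform_value(times, spec)
  osc_t <- sin(2 * pi * (times - T) / T)

  with_fixed_seed(seed, {
    pressure <- outer(p_profile, w) +
      matrix(stats::rnorm(nv * spec$n_steps, 0, spec$pressure_noise_sd_pa),
             nv, spec$n_steps)
    wss <- array(NA_real_, c(nv, 3, spec$n_steps))
    for (k in seq_len(spec$n_steps)) {
      wss[, , k] <- w[k] * f_static + osc_t[k] * osc_static +
        matrix(stats::rnorm(nv * 3, 0, spec$wss_noise_sd_pa), nv, 3)
    }
    field_series(times, pressure, wss, period_T = T)
  })
}

#' Generate null fields with no region-dependent structure
#'
#' Same scales and waveform as [make_fields()] but without the pressure
#' bump, the low-WSS patch, the planted sources and the oscillatory
#' component, and with a spatially uniform pressure level, so bleb and
#' non-bleb vertices share one distribution. Used for type-I-error
#' calibration of the region comparison.
#'
#' @inheritParams make_fields
#' @return a [field_series()] over the second cycle.
#' @export
make_null_fields <- function(mesh, truth, seed = truth$spec$seed) {
  spec <- truth$spec
  parts <- synthetic_static_parts(mesh, truth)
  nv <- n_vertices(mesh)
  mag <- ifelse(seq_len(nv) %in% parts$dome, spec$tau_dome_pa,
                spec$tau_tube_pa)
  f_static <- parts$base_dir * mag
  T <- spec$period_T_s
  times <- T + seq(0, T, length.out = spec$n_steps)
  w <- waveform_value(times, spec)
  with_fixed_seed(seed, {
    pressure <- outer(rep(spec$base_pressure_pa, nv), w) +
      matrix(stats::rnorm(nv * spec$n_steps, 0, spec$pressure_noise_sd_pa),
             nv, spec$n_steps)
    wss <- array(NA_real_, c(nv, 3, spec$n_steps))
    for (k in seq_len(spec$n_steps)) {
      wss[, , k] <- w[k] * f_static +
        matrix(stats::rnorm(nv * 3, 0, spec$wss_noise_sd_pa), nv, 3)
    }
    field_series(times, pressure, wss, period_T = T)
  })
}
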