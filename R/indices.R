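#' Define the inlet reference cross-section
#'
#' Selects the mesh vertices lying within `thickness/2` of a plane through
#' the parent vessel, conventionally placed 1 mm proximal to the aneurysm
#' neck. The inlet plane supplies the reference averages used to normalize
#' pressure and WSS.
#'
#' @param mesh a [surface_mesh()].
#' @param origin length-3 point on the plane (mm).
#' @param normal length-3 plane normal (normalized internally).
#' @param thickness slab thickness in mm; vertices within `thickness/2` of
#'   the plane are members.
#' @return An object of class `inlet_plane`: list with `origin`, `normal`
#'   (unit) and `member_vertices` (1-based indices).
#' @export
define_inlet_plane <- function(mesh, origin, normal, thickness = 0.5) {
  normal <- as.numeric(normal)
  len <- sqrt(sum(normal^2))
  if (len == 0) stop("plane normal must be nonzero")
  normal <- normal / len
  d <- abs((mesh$vertices - matrix(origin, n_vertices(mesh), 3,
                                   byrow = TRUE)) %*% normal)
  members <- which(d <= thickness / 2)
  if (length(members) == 0L) {
    stop("empty inlet: no vertices within ", thickness / 2, " mm of the plane")
  }
  structure(list(origin = as.numeric(origin), normal = normal,
                 thickness = thickness,
                 member_vertices = as.integer(members)),
            class = "inlet_plane")
}

#' Peak-systole snapshot selection
#'
#' Returns the time of maximum flow rate within a given cardiac cycle of an
#' inlet flow waveform; the analysis convention is the peak systole of the
#' second simulated cycle. Ties are broken toward the earliest time.
#'
#' @param waveform data.frame with columns `time` (s) and `flow` (arbitrary
#'   flow-rate units), sampled over the simulated cycles.
#' @param cycle_index 1-based index of the cycle to search.
#' @param period_T cycle period in s.
#' @return the snapshot time in s.
#' @export
select_peak_systole <- function(waveform, cycle_index, period_T) {
  if (!all(c("time", "flow") %in% names(waveform))) {
    stop("waveform must have columns time and flow")
  }
  lo <- (cycle_index - 1) * period_T
  hi <- cycle_index * period_T
  sel <- waveform$time >= lo - 1e-12 & waveform$time <= hi + 1e-12
  if (!any(sel)) {
    stop("range error: waveform does not cover cycle ", cycle_index)
  }
  t_sel <- waveform$time[sel]
  f_sel <- waveform$flow[sel]
  t_sel[which.max(f_sel)] # which.max returns the first maximum: earliest tie
}

# Index of the field-series time step closest to a snapshot time.
snapshot_step <- function(fs, snapshot_time) {
  k <- which.min(abs(fs$times - snapshot_time))
  if (abs(fs$times[k] - snapshot_time) > 1e-6) {
    warning("snapshot time ", snapshot_time,
            " not on the field time grid; using nearest step t = ",
            fs$times[k])
  }
  k
}

#' Area-weighted inlet average of a field
#'
#' Averages a per-vertex scalar field (pressure) or the magnitude of a
#' per-vertex vector field (WSS) over the inlet-plane member vertices.
#' Weights are the per-vertex surface areas (one third of incident face
#' area); `weighted = FALSE` gives the plain vertex-count mean.
#'
#' @param mesh a [surface_mesh()].
#' @param inlet an [define_inlet_plane()] result.
#' @param field numeric vector (length n) or n x 3 matrix.
#' @param weighted use area weights (default) or a plain mean.
#' @return the scalar average (Pa for pressure or WSS magnitude).
#' @export
inlet_average <- function(mesh, inlet, field, weighted = TRUE) {
  idx <- inlet$member_vertices
  if (length(idx) == 0L) stop("empty inlet")
  vals <- if (is.matrix(field)) {
    sqrt(rowSums(field[idx, , drop = FALSE]^2))
  } else {
    field[idx]
  }
  if (weighted) {
    w <- vertex_areas(mesh)[idx]
    if (sum(w) <= 0) stop("degenerate inlet: zero total area weight")
    sum(w * vals) / sum(w)
  } else {
    mean(vals)
  }
}

#' Normalize a field by its inlet reference
#'
#' Division by the inlet-plane average removes dependence on the inflow
#' boundary conditions: normalized pressure = pressure / inlet-average
#' pressure, normalized WSS = |WSS| / inlet-average |WSS|.
#'
#' @param value numeric value(s) in Pa.
#' @param reference positive inlet average in Pa.
#' @return dimensionless value(s).
#' @export
normalize_field <- function(value, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("normalization error: inlet reference must be a positive scalar")
  }
  value / reference
}

#' Time-averaged wall shear stress at one point
#'
#' TAWSS = (1/T) * integral over the cycle of |tau(t)| dt, computed with the
#' trapezoidal rule on the supplied (possibly non-uniform) time grid.
#'
#' @param wss numeric matrix n_times x 3, the WSS vector history tau(t) in Pa.
#' @param times numeric vector of times in s.
#' @param period_T cycle period in s.
#' @return TAWSS in Pa (non-negative).
#' @export
tawss <- function(wss, times, period_T) {
  wss <- as.matrix(wss)
  if (length(times) < 2L) {
    stop("insufficient data: TAWSS needs at least 2 time samples")
  }
  mag <- sqrt(rowSums(wss^2))
  pracma::trapz(times, mag) / period_T
}

#' Oscillatory shear index at one point
#'
#' OSI = 0.5 * (1 - |integral of tau dt| / integral of |tau| dt), in
#' [0, 0.5]: 0 for a unidirectional WSS vector, 0.5 for perfect reversal.
#' A WSS history that is identically zero has undefined OSI and yields
#' `NA` (such points are excluded from the statistics with their count
#' reported).
#'
#' @inheritParams tawss
#' @return dimensionless OSI in [0, 0.5], or `NA` when undefined.
#' @export
osi <- function(wss, times, period_T) {
  wss <- as.matrix(wss)
  if (length(times) < 2L) {
    stop("insufficient data: OSI needs at least 2 time samples")
  }
  mag_int <- pracma::trapz(times, sqrt(rowSums(wss^2)))
  if (mag_int <= 0) return(NA_real_)
  vec_int <- vapply(1:3, function(j) pracma::trapz(times, wss[, j]),
                    numeric(1))
  val <- 0.5 * (1 - sqrt(sum(vec_int^2)) / mag_int)
  min(max(val, 0), 0.5) # clamp floating-point leakage
}

#' Per-vertex hemodynamic index fields
#'
#' Computes, for every mesh vertex, the four parameters of the multipoint
#' analysis: normalized pressure and normalized WSS at the peak-systole
#' snapshot, and TAWSS and OSI over the full supplied cycle.
#'
#' @param mesh a [surface_mesh()].
#' @param fs a [field_series()] aligned to `mesh`.
#' @param inlet an inlet plane from [define_inlet_plane()].
#' @param snapshot_time the peak-systole time (s), normally from
#'   [select_peak_systole()].
#' @param weighted area-weight the inlet averages (default TRUE).
#' @return list with per-vertex numeric vectors `normalized_pressure`,
#'   `normalized_wss`, `tawss`, `osi`, plus the `inlet_reference` (list
#'   with `pressure_ave_inlet`, `wss_ave_inlet`, `snapshot_time`).
#' @export
compute_index_fields <- function(mesh, fs, inlet, snapshot_time,
                                 weighted = TRUE) {
  check_field_alignment(fs, mesh)
  k <- snapshot_step(fs, snapshot_time)
  p_snap <- fs$pressure[, k]
  wss_snap <- fs$wss[, , k]
  p_ref <- inlet_average(mesh, inlet, p_snap, weighted = weighted)
  if (p_ref <= 0) {
    stop("normalization error: inlet-average pressure is not positive")
  }
  w_ref <- inlet_average(mesh, inlet, wss_snap, weighted = weighted)
  if (w_ref <= 0) {
    stop("normalization error: inlet-average WSS is not positive")
  }
  nv <- n_vertices(mesh)
  mags <- sqrt(fs$wss[, 1, ]^2 + fs$wss[, 2, ]^2 + fs$wss[, 3, ]^2)
  # trapezoid weights for the shared time grid
  tw <- trapezoid_weights(fs$times)
  mag_int <- as.vector(mags %*% tw)
  vx <- as.vector(fs$wss[, 1, ] %*% tw)
  vy <- as.vector(fs$wss[, 2, ] %*% tw)
  vz <- as.vector(fs$wss[, 3, ] %*% tw)
  vec_int <- sqrt(vx^2 + vy^2 + vz^2)
  osi_v <- rep(NA_real_, nv)
  pos <- mag_int > 0
  osi_v[pos] <- pmin(pmax(0.5 * (1 - vec_int[pos] / mag_int[pos]), 0), 0.5)
  list(
    normalized_pressure = p_snap / p_ref,
    normalized_wss = sqrt(rowSums(wss_snap^2)) / w_ref,
    tawss = mag_int / fs$period_T,
    osi = osi_v,
    inlet_reference = list(pressure_ave_inlet = p_ref,
                           wss_ave_inlet = w_ref,
                           snapshot_time = fs$times[k])
  )
}

trapezoid_weights <- function(times) {
  n <- length(times)
  if (n < 2L) stop("insufficient data: need at least 2 time samples")
  dt <- diff(times)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dt[-length(dt)] + dt[-1]) / 2
  w
}
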