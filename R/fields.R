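#' Time-resolved surface fields over one cardiac cycle
#'
#' Container for per-vertex pressure scalars (Pa) and wall-shear-stress
#' (WSS) vectors (Pa) sampled at a set of strictly increasing times that
#' span at most one cycle of period `period_T` (s).
#'
#' @param times numeric vector of times in s, strictly increasing,
#'   `times[1] >= 0`, spanning at most `period_T`.
#' @param pressure numeric matrix, n_vertices x n_times, in Pa.
#' @param wss numeric array, n_vertices x 3 x n_times, in Pa.
#' @param period_T cycle period in s.
#'
#' @return An object of class `field_series`.
#' @export
field_series <- function(times, pressure, wss, period_T) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("at least one time step required")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("ordering error: times must be strictly increasing")
  }
  if (times[1] < 0) stop("times must be non-negative")
  if (!is.numeric(period_T) || period_T <= 0) stop("period_T must be positive")
  if (times[length(times)] - times[1] > period_T + 1e-9) {
    stop("times span more than one period")
  }
  pressure <- as.matrix(pressure)
  if (ncol(pressure) != length(times)) {
    stop("alignment error: pressure must have one column per time step")
  }
  if (length(dim(wss)) != 3L || dim(wss)[2] != 3L ||
        dim(wss)[3] != length(times)) {
    stop("alignment error: wss must be n_vertices x 3 x n_times")
  }
  if (dim(wss)[1] != nrow(pressure)) {
    stop("alignment error: pressure and wss disagree on vertex count")
  }
  structure(list(times = times, pressure = pressure, wss = wss,
                 period_T = period_T),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat("field_series:", nrow(x$pressure), "vertices,", length(x$times),
      "time steps over", sprintf("%.3f", diff(range(x$times))),
      "s (period", x$period_T, "s)\n")
  invisible(x)
}

check_field_alignment <- function(fs, mesh) {
  if (nrow(fs$pressure) != n_vertices(mesh)) {
    stop("alignment error: field has ", nrow(fs$pressure),
         " vertices but mesh has ", n_vertices(mesh))
  }
  invisible(TRUE)
}

#' Read and write a field series in the plain-text directory layout
#'
#' The layout is a directory holding `meta.json` (`period_T`, `n_vertices`,
#' `n_steps`) and `fields.csv`, a long table with columns
#' `time, vertex, pressure, wss_x, wss_y, wss_z` (1-based vertex ids).
#'
#' @param path directory path.
#' @param mesh the [surface_mesh()] the fields belong to; vertex counts are
#'   checked at every time step.
#' @param fs a [field_series()] (write only).
#' @return `load_field_series` returns a [field_series()];
#'   `write_field_series` returns `path` invisibly.
#' @export
load_field_series <- function(path, mesh) {
  meta_path <- file.path(path, "meta.json")
  csv_path <- file.path(path, "fields.csv")
  if (!file.exists(meta_path) || !file.exists(csv_path)) {
    stop("field-series directory must contain meta.json and fields.csv")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- data.table::fread(csv_path)
  times <- sort(unique(d$time))
  nv <- n_vertices(mesh)
  n_steps <- length(times)
  if (nrow(d) != nv * n_steps) {
    stop("alignment error: expected ", nv * n_steps,
         " field records, found ", nrow(d))
  }
  cnt <- table(d$time)
  if (any(cnt != nv)) {
    stop("alignment error: a time step does not cover every vertex")
  }
  if (!is.null(meta$n_steps) && meta$n_steps != n_steps) {
    stop("ordering error: meta.json step count disagrees with fields.csv ",
         "(duplicate or missing timestamps)")
  }
  data.table::setorderv(d, c("time", "vertex"))
  pressure <- matrix(d$pressure, nrow = nv, ncol = n_steps)
  wss <- array(NA_real_, c(nv, 3, n_steps))
  wss[, 1, ] <- matrix(d$wss_x, nrow = nv)
  wss[, 2, ] <- matrix(d$wss_y, nrow = nv)
  wss[, 3, ] <- matrix(d$wss_z, nrow = nv)
  field_series(times, pressure, wss, period_T = meta$period_T)
}

#' @rdname load_field_series
#' @export
write_field_series <- function(fs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nv <- nrow(fs$pressure)
  n_steps <- length(fs$times)
  d <- data.table::data.table(
    time = rep(fs$times, each = nv),
    vertex = rep(seq_len(nv), n_steps),
    pressure = as.vector(fs$pressure),
    wss_x = as.vector(fs$wss[, 1, ]),
    wss_y = as.vector(fs$wss[, 2, ]),
    wss_z = as.vector(fs$wss[, 3, ]))
  data.table::fwrite(d, file.path(path, "fields.csv"))
  jsonlite::write_json(
    list(period_T = fs$period_T, n_vertices = nv, n_steps = n_steps),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write a field series as a multi-file legacy-VTK sequence
#'
#' One ASCII VTK polydata file per time step (`step_000.vtk`, ...), each
#' carrying the mesh plus a `pressure` scalar and a `wss` vector field, and
#' an `index.json` listing the files, their times and the cycle period.
#'
#' @inheritParams load_field_series
#' @return `load_vtk_series` a [field_series()]; `write_vtk_series` the
#'   directory path, invisibly.
#' @export
load_vtk_series <- function(path, mesh) {
  idx_path <- file.path(path, "index.json")
  if (!file.exists(idx_path)) stop("VTK series directory lacks index.json")
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  nv <- n_vertices(mesh)
  n_steps <- length(idx$files)
  if (is.unsorted(idx$times, strictly = TRUE)) {
    stop("ordering error: index times must be strictly increasing")
  }
  pressure <- matrix(NA_real_, nv, n_steps)
  wss <- array(NA_real_, c(nv, 3, n_steps))
  for (k in seq_len(n_steps)) {
    vt <- read_vtk_polydata(file.path(path, idx$files[k]))
    if (n_vertices(vt$mesh) != nv) {
      stop("alignment error: step ", k, " has ", n_vertices(vt$mesh),
           " vertices, mesh has ", nv)
    }
    if (is.null(vt$point_data$pressure) || is.null(vt$point_data$wss)) {
      stop("VTK step file lacks pressure/wss point data")
    }
    pressure[, k] <- vt$point_data$pressure
    wss[, , k] <- vt$point_data$wss
  }
  field_series(idx$times, pressure, wss, period_T = idx$period_T)
}

#' @rdname load_vtk_series
#' @export
write_vtk_series <- function(fs, mesh, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("step_%03d.vtk", seq_along(fs$times) - 1L)
  for (k in seq_along(fs$times)) {
    write_vtk_polydata(
      mesh, file.path(path, files[k]),
      point_data = list(pressure = fs$pressure[, k],
                        wss = fs$wss[, , k]))
  }
  jsonlite::write_json(
    list(files = files, times = fs$times, period_T = fs$period_T),
    file.path(path, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
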