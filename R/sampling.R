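# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Distribute points evenly on a surface at a fixed spacing
#'
#' The multipoint method's sampling step: a Poisson-disk distribution at
#' target spacing `spacing` (mm) over the whole mesh or a labelled
#' subregion. A dense area-weighted candidate set is drawn on the faces and
#' thinned greedily (dart throwing with a cell grid), so that the minimum
#' pairwise Euclidean (3D chord) distance is at least
#' `spacing * (1 - spacing_tolerance)` and the surface is saturated: no
#' further point could be added at distance `spacing` from all kept points.
#' The result is deterministic for a fixed `seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param domain_label optional character vector of region labels; only
#'   faces whose three vertices all carry one of these labels are sampled.
#'   `NULL` samples the whole mesh.
#' @param spacing target spacing in mm (the study value is 0.5).
#' @param seed integer RNG seed.
#' @param spacing_tolerance fractional spacing slack (default 0.05).
#' @param candidate_density candidate points per `spacing^2` of area
#'   (default 40, enough to saturate the disk packing).
#' @return An object of class `sample_point_set`: list with `points`
#'   (k x 3 mm), `face` (anchor face index), `bary` (k x 3 barycentric
#'   coordinates), `region` (per-point label or `NA`), `records`
#'   (data.frame of per-point hemodynamic measurements, initially empty),
#'   `spacing` and `seed`.
#' @export
distribute_points <- function(mesh, domain_label = NULL, spacing = 0.5,
                              seed = 1L, spacing_tolerance = 0.05,
                              candidate_density = 40) {
  if (spacing <= 0) stop("spacing must be positive")
  faces_keep <- seq_len(n_faces(mesh))
  if (!is.null(domain_label)) {
    if (is.null(mesh$region)) stop("mesh carries no region labels")
    vin <- mesh$region %in% domain_label
    fin <- vin[mesh$faces[, 1]] & vin[mesh$faces[, 2]] & vin[mesh$faces[, 3]]
    faces_keep <- which(fin)
  }
  fa <- face_areas(mesh)[faces_keep]
  total_area <- sum(fa)
  if (length(faces_keep) == 0L || total_area <= 0) {
    stop("empty domain: selected subregion has no area")
  }
  n_cand <- max(64L, ceiling(candidate_density * total_area / spacing^2))
  r <- spacing * (1 - spacing_tolerance)

  cand <- with_fixed_seed(seed, {
    fidx <- sample.int(length(faces_keep), n_cand, replace = TRUE,
                       prob = fa / total_area)
    # uniform barycentric coordinates via the square-root trick
    r1 <- sqrt(stats::runif(n_cand))
    r2 <- stats::runif(n_cand)
    b <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
    list(face = faces_keep[fidx], bary = b)
  })
  v <- mesh$vertices
  f <- mesh$faces[cand$face, , drop = FALSE]
  pts <- cand$bary[, 1] * v[f[, 1], , drop = FALSE] +
    cand$bary[, 2] * v[f[, 2], , drop = FALSE] +
    cand$bary[, 3] * v[f[, 3], , drop = FALSE]

  keep <- poisson_thin(pts, r)
  sp <- structure(
    list(points = pts[keep, , drop = FALSE],
         face = cand$face[keep],
         bary = cand$bary[keep, , drop = FALSE],
         region = rep(NA_character_, length(keep)),
         records = NULL,
         spacing = spacing, seed = seed,
         spacing_tolerance = spacing_tolerance),
    class = "sample_point_set")
  sp
}

# Greedy dart throwing: keep candidate i when no already-kept point lies
# within distance r. A 3D cell grid of edge r limits the search to the 27
# neighbouring cells.
poisson_thin <- function(pts, r) {
  n <- nrow(pts)
  cell <- floor(sweep(pts, 2, apply(pts, 2, min)) / r)
  storage.mode(cell) <- "integer"
  key_of <- function(cx, cy, cz) paste(cx, cy, cz)
  grid <- new.env(parent = emptyenv(), size = n)
  kept <- integer(0)
  r2 <- r * r
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(n)) {
    ci <- cell[i, ]
    ok <- TRUE
    for (o in seq_len(27L)) {
      k <- key_of(ci[1] + offs[o, 1], ci[2] + offs[o, 2], ci[3] + offs[o, 3])
      neigh <- grid[[k]]
      if (!is.null(neigh)) {
        d2 <- (pts[neigh, 1] - pts[i, 1])^2 +
          (pts[neigh, 2] - pts[i, 2])^2 +
          (pts[neigh, 3] - pts[i, 3])^2
        if (any(d2 < r2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      kept <- c(kept, i)
      k <- key_of(ci[1], ci[2], ci[3])
      grid[[k]] <- c(grid[[k]], i)
    }
  }
  kept
}

#' @export
print.sample_point_set <- function(x, ...) {
  cat("sample_point_set:", nrow(x$points), "points at",
      x$spacing, "mm spacing (seed", paste0(x$seed, ")"), "\n")
  if (!all(is.na(x$region))) {
    cat("  regions:", paste(names(table(x$region)), table(x$region),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Measure a per-vertex field at the sample points
#'
#' Values are interpolated with the barycentric coordinates of each point's
#' anchor face, so measurement is exact for fields linear in position on
#' each face.
#'
#' @param points a [distribute_points()] result.
#' @param mesh the mesh the points were sampled from.
#' @param field per-vertex numeric vector (scalar field) or n x 3 matrix
#'   (vector field).
#' @return numeric vector (length k) or k x 3 matrix of per-point values.
#' @export
measure_at_points <- function(points, mesh, field) {
  f <- mesh$faces
  if (any(points$face < 1L | points$face > nrow(f))) {
    stop("integrity error: sample point anchored to an invalid face")
  }
  tri <- f[points$face, , drop = FALSE]
  b <- points$bary
  if (is.matrix(field)) {
    if (nrow(field) != n_vertices(mesh)) {
      stop("alignment error: field length does not match mesh")
    }
    b[, 1] * field[tri[, 1], , drop = FALSE] +
      b[, 2] * field[tri[, 2], , drop = FALSE] +
      b[, 3] * field[tri[, 3], , drop = FALSE]
  } else {
    if (length(field) != n_vertices(mesh)) {
      stop("alignment error: field length does not match mesh")
    }
    b[, 1] * field[tri[, 1]] + b[, 2] * field[tri[, 2]] +
      b[, 3] * field[tri[, 3]]
  }
}

#' Label sample points by region
#'
#' Each point inherits the majority label among its anchor face's three
#' vertex labels; 2:1 splits take the majority and bleb/nonbleb ties (which
#' cannot occur with three vertices but can with missing labels) resolve
#' toward `bleb`, the conservative choice when characterising the
#' bleb-formation area.
#'
#' @param points a [distribute_points()] result.
#' @param mesh a mesh carrying a bleb/nonbleb vertex labelling over the
#'   sampled domain.
#' @return `points` with its `region` field filled.
#' @export
label_points <- function(points, mesh) {
  if (is.null(mesh$region)) stop("labelling error: mesh has no region labels")
  tri <- mesh$faces[points$face, , drop = FALSE]
  labs <- matrix(mesh$region[tri], ncol = 3)
  out <- character(nrow(labs))
  for (i in seq_len(nrow(labs))) {
    li <- labs[i, ]
    li <- li[li %in% c("bleb", "nonbleb")]
    if (length(li) == 0L) {
      stop("labelling error: sample point on a face without bleb/nonbleb ",
           "vertex labels")
    }
    nb <- sum(li == "bleb")
    nn <- sum(li == "nonbleb")
    out[i] <- if (nb >= nn) "bleb" else "nonbleb" # ties toward bleb
  }
  points$region <- out
  points
}

#' Export sample points and their records as a data.frame
#'
#' @param points a `sample_point_set`, optionally with measurement records.
#' @return data.frame with one row per point: `point_id`, coordinates,
#'   anchor face, region and any measured parameters.
#' @export
as.data.frame.sample_point_set <- function(x, ...) {
  d <- data.frame(point_id = seq_len(nrow(x$points)),
                  x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                  face_id = x$face, region = x$region,
                  stringsAsFactors = FALSE)
  if (!is.null(x$records)) d <- cbind(d, x$records)
  d
}
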