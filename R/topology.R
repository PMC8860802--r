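#' Project per-vertex vectors into the local tangent plane
#'
#' WSS is tangential by definition; CFD exports carry small numerical
#' normal components which this removes: `v - (v . n) n` per vertex.
#'
#' @param mesh a [surface_mesh()].
#' @param vectors n x 3 matrix of per-vertex vectors (Pa).
#' @return n x 3 matrix orthogonal to the vertex normals.
#' @export
tangential_projection <- function(mesh, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != n_vertices(mesh)) {
    stop("alignment error: vectors must have one row per vertex")
  }
  n <- mesh$normals
  vectors - n * as.vector(rowSums(vectors * n))
}

#' Discrete surface divergence of a tangential vector field
#'
#' Per-face divergence from linear (hat) shape functions: on each triangle
#' the field is interpolated linearly from its corners, giving the constant
#' div_f = sum_i F_i . grad(phi_i); per-vertex values are the area-weighted
#' average over incident faces. Units Pa/mm for a WSS field on a mm mesh.
#' Degenerate (zero-area) faces are excluded with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param tangential n x 3 matrix, the tangential field.
#' @return numeric vector of per-vertex divergence values (Pa/mm).
#' @export
surface_divergence <- function(mesh, tangential) {
  tangential <- as.matrix(tangential)
  if (nrow(tangential) != n_vertices(mesh)) {
    stop("alignment error: field must have one row per vertex")
  }
  v <- mesh$vertices
  f <- mesh$faces
  fnv <- face_normal_vectors(mesh) # 2A * unit normal
  a2 <- sqrt(rowSums(fnv^2))       # 2A
  keep <- a2 > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " degenerate zero-area face(s) excluded from ",
            "divergence")
  }
  nhat <- fnv[keep, , drop = FALSE] / a2[keep]
  fk <- f[keep, , drop = FALSE]
  area <- a2[keep] / 2
  # grad(phi_i) = (nhat x e_i) / (2A), e_i the edge opposite corner i
  e1 <- v[fk[, 3], , drop = FALSE] - v[fk[, 2], , drop = FALSE]
  e2 <- v[fk[, 1], , drop = FALSE] - v[fk[, 3], , drop = FALSE]
  e3 <- v[fk[, 2], , drop = FALSE] - v[fk[, 1], , drop = FALSE]
  g1 <- row_cross(nhat, e1) / a2[keep]
  g2 <- row_cross(nhat, e2) / a2[keep]
  g3 <- row_cross(nhat, e3) / a2[keep]
  div_face <- rowSums(tangential[fk[, 1], , drop = FALSE] * g1) +
    rowSums(tangential[fk[, 2], , drop = FALSE] * g2) +
    rowSums(tangential[fk[, 3], , drop = FALSE] * g3)
  num <- numeric(n_vertices(mesh))
  den <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    s <- tapply(div_face * area, fk[, j], sum)
    idx <- as.integer(names(s))
    num[idx] <- num[idx] + as.numeric(s)
    sw <- tapply(area, fk[, j], sum)
    den[idx] <- den[idx] + as.numeric(sw)
  }
  out <- rep(NA_real_, n_vertices(mesh))
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

#' Detect centers of divergent WSS vectors
#'
#' A divergence center (a source of the tangential WSS field, around which
#' WSS vectors point radially outward) is a vertex that (a) is a one-ring
#' local maximum of surface divergence above the `min_divergence_percentile`
#' percentile of the searched domain, (b) has outward-pointing field on at
#' least `outflow_fraction_threshold` of its one-ring edges, and (c) is
#' separated from stronger accepted centers by at least `min_separation_mm`.
#' Boundary (neck-ring) vertices are excluded. Centers are returned sorted
#' by descending divergence; an empty result is valid.
#'
#' @param mesh a [surface_mesh()].
#' @param tangential n x 3 tangential WSS field at the analysis snapshot.
#' @param divergence per-vertex divergence, normally from
#'   [surface_divergence()].
#' @param domain_label optional region labels restricting the search (e.g.
#'   `c("bleb", "nonbleb")` for the dome); `NULL` searches all vertices.
#' @param min_divergence_percentile percentile threshold (default 95).
#' @param min_separation_mm minimum center separation (default 1.0 mm).
#' @param outflow_fraction_threshold required outward-edge fraction
#'   (default 0.8).
#' @return data.frame of class `divergence_centers`: one row per center
#'   with `center_id`, `vertex_id`, coordinates, `divergence` (Pa/mm) and
#'   `region`.
#' @export
find_divergence_centers <- function(mesh, tangential, divergence,
                                    domain_label = NULL,
                                    min_divergence_percentile = 95,
                                    min_separation_mm = 1.0,
                                    outflow_fraction_threshold = 0.8) {
  tangential <- as.matrix(tangential)
  nv <- n_vertices(mesh)
  if (length(divergence) != nv || nrow(tangential) != nv) {
    stop("alignment error: fields must have one value per vertex")
  }
  domain <- rep(TRUE, nv)
  if (!is.null(domain_label)) {
    if (is.null(mesh$region)) stop("mesh carries no region labels")
    domain <- mesh$region %in% domain_label
  }
  domain[boundary_vertices(mesh)] <- FALSE
  domain[is.na(divergence)] <- FALSE
  if (!any(domain)) return(empty_centers())
  thr <- stats::quantile(divergence[domain],
                         min_divergence_percentile / 100, na.rm = TRUE)
  rings <- vertex_one_rings(mesh)
  cand <- which(domain & divergence >= thr & divergence > 0)
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    ring <- rings[[i]]
    if (length(ring) == 0L) next
    dring <- divergence[ring]
    if (any(!is.na(dring) & dring > divergence[i])) next # not a local max
    # outward flow along one-ring edges: the field at each ring vertex
    # must point away from the candidate (the candidate's own field is
    # near zero at a source and would only add noise)
    e <- mesh$vertices[ring, , drop = FALSE] -
      matrix(mesh$vertices[i, ], length(ring), 3, byrow = TRUE)
    outward <- rowSums(tangential[ring, , drop = FALSE] * e) > 0
    if (mean(outward) < outflow_fraction_threshold) next
    keep[ii] <- TRUE
  }
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty_centers())
  cand <- cand[order(-divergence[cand])]
  accepted <- integer(0)
  for (i in cand) {
    if (length(accepted) > 0L) {
      d <- sqrt(rowSums((mesh$vertices[accepted, , drop = FALSE] -
                           matrix(mesh$vertices[i, ], length(accepted), 3,
                                  byrow = TRUE))^2))
      if (any(d < min_separation_mm)) next
    }
    accepted <- c(accepted, i)
  }
  out <- data.frame(
    center_id = seq_along(accepted),
    vertex_id = accepted,
    x = mesh$vertices[accepted, 1],
    y = mesh$vertices[accepted, 2],
    z = mesh$vertices[accepted, 3],
    divergence = divergence[accepted],
    region = if (is.null(mesh$region)) NA_character_
             else mesh$region[accepted],
    stringsAsFactors = FALSE)
  class(out) <- c("divergence_centers", "data.frame")
  out
}

empty_centers <- function() {
  out <- data.frame(center_id = integer(0), vertex_id = integer(0),
                    x = numeric(0), y = numeric(0), z = numeric(0),
                    divergence = numeric(0), region = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_centers", "data.frame")
  out
}

#' Flag the sample points that represent divergence centers
#'
#' Each detected center is assigned to the nearest sample point (Euclidean
#' distance; ties break toward the lower point id), whose record gets
#' `is_center = TRUE`. A point may represent at most one center; two
#' centers mapping to the same point indicate the sampling is too sparse
#' and raise an error.
#'
#' @param points a `sample_point_set`.
#' @param centers a [find_divergence_centers()] result.
#' @return `points` with an `is_center` logical column in its records and
#'   the assigned point id stored in `attr(points$records, "center_points")`.
#' @export
flag_center_points <- function(points, centers) {
  k <- nrow(points$points)
  is_center <- rep(FALSE, k)
  assigned <- integer(0)
  if (nrow(centers) > 0L) {
    for (ci in seq_len(nrow(centers))) {
      d <- sqrt((points$points[, 1] - centers$x[ci])^2 +
                  (points$points[, 2] - centers$y[ci])^2 +
                  (points$points[, 3] - centers$z[ci])^2)
      pid <- which.min(d) # first minimum: lower point id wins ties
      if (is_center[pid]) {
        stop("assignment error: two divergence centers map to the same ",
             "sample point; increase sampling density")
      }
      is_center[pid] <- TRUE
      assigned <- c(assigned, pid)
    }
  }
  if (is.null(points$records)) {
    points$records <- data.frame(is_center = is_center)
  } else {
    points$records$is_center <- is_center
  }
  attr(points$records, "center_points") <- assigned
  points
}
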