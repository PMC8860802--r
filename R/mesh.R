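#' Triangulated vascular surface mesh
#'
#' Construct and validate a `surface_mesh`, the container used throughout the
#' package for aneurysm and parent-vessel surfaces. Coordinates are in mm.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based triangle vertex indices.
#' @param region optional character vector of length n with per-vertex labels
#'   from `c("bleb", "nonbleb", "vessel", "inlet")`; `NA` allowed.
#' @param normals optional n x 3 matrix of outward unit vertex normals;
#'   computed from area-weighted face normals when absent.
#'
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `normals` and `region`.
#' @export
surface_mesh <- function(vertices, faces, region = NULL, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) {
    stop("unsupported topology: faces must be triangles (3 indices per face)")
  }
  n <- nrow(vertices)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > n)) {
    stop("face references an invalid vertex index")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3])) {
    stop("unsupported topology: face with repeated vertex indices")
  }
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != n) stop("region must have one label per vertex")
    bad <- !is.na(region) & !region %in% c("bleb", "nonbleb", "vessel", "inlet")
    if (any(bad)) stop("unknown region label: ", region[which(bad)[1]])
  }
  mesh <- structure(
    list(vertices = vertices, faces = faces, normals = NULL, region = region),
    class = "surface_mesh"
  )
  if (is.null(normals)) {
    mesh$normals <- vertex_normals(mesh)
  } else {
    normals <- as.matrix(normals)
    dimnames(normals) <- NULL
    if (!all(dim(normals) == c(n, 3L))) stop("normals must be n x 3")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) stop("vertex normals must have unit length")
    mesh$normals <- normals
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  if (!is.null(x$region)) {
    cat("  region labels:",
        paste(names(table(x$region)), table(x$region), collapse = ", "), "\n")
  }
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# Cross product of rows of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Unnormalized face normals (2 * area * unit normal), m x 3.
face_normal_vectors <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  row_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
            v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
}

#' Triangle areas of a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of face areas in mm^2.
#' @export
face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_normal_vectors(mesh)^2))
}

#' Per-vertex area weights (one third of incident face area)
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of vertex areas in mm^2.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  w <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    s <- tapply(fa / 3, mesh$faces[, j], sum)
    idx <- as.integer(names(s))
    w[idx] <- w[idx] + as.numeric(s)
  }
  w
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit length.
#'
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normal_vectors(mesh) # already area-weighted
  vn <- matrix(0, n_vertices(mesh), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      s <- tapply(fn[, k], mesh$faces[, j], sum)
      idx <- as.integer(names(s))
      vn[idx, k] <- vn[idx, k] + as.numeric(s)
    }
  }
  len <- sqrt(rowSums(vn^2))
  if (any(len == 0)) stop("isolated or degenerate vertex: zero normal")
  vn / len
}

# Unique undirected edges as a 2-column matrix plus the count of incident
# faces per edge.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  first <- !duplicated(key)
  list(edges = e[first, , drop = FALSE],
       n_faces = as.integer(tab[key[first]]))
}

#' Boundary vertices of an open mesh
#'
#' A vertex is a boundary vertex when it touches an edge shared by exactly
#' one face (the neck ring of a dome patch, the ends of a tube).
#'
#' @param mesh a `surface_mesh`.
#' @return integer vector of boundary vertex indices (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh)
  b <- ed$edges[ed$n_faces == 1L, , drop = FALSE]
  sort(unique(as.integer(b)))
}

# One-ring neighbour list: for each vertex, the sorted indices of adjacent
# vertices.
vertex_one_rings <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  n <- n_vertices(mesh)
  rings <- vector("list", n)
  half <- split(ed[, 2], ed[, 1])
  for (nm in names(half)) {
    i <- as.integer(nm)
    rings[[i]] <- c(rings[[i]], half[[nm]])
  }
  half <- split(ed[, 1], ed[, 2])
  for (nm in names(half)) {
    i <- as.integer(nm)
    rings[[i]] <- c(rings[[i]], half[[nm]])
  }
  lapply(rings, function(r) sort(unique(r)))
}

# Map from vertex index to indices of incident faces.
vertex_face_index <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  split(rep(seq_len(m), 3), as.vector(f))
}

#' Apply a rigid transformation to a mesh
#'
#' Utility used mainly in invariance tests: rotates by `rotation` (3 x 3
#' orthonormal) and then translates by `translation`.
#'
#' @param mesh a `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric.
#' @return the transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$faces, region = mesh$region,
               normals = mesh$normals %*% t(rotation))
}
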