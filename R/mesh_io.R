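# Region labels are stored in files as small integer codes.
.region_levels <- c("vessel", "inlet", "nonbleb", "bleb")

region_to_code <- function(region) {
  code <- match(region, .region_levels) - 1L
  code[is.na(region)] <- -1L
  code
}

code_to_region <- function(code) {
  region <- rep(NA_character_, length(code))
  ok <- code >= 0L & code <= 3L
  region[ok] <- .region_levels[code[ok] + 1L]
  region
}

infer_mesh_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         stl = "stl", ply = "ply", vtk = "vtk", vtp = "vtk",
         stop("cannot infer mesh format from extension: ", path))
}

#' Load a triangulated surface mesh
#'
#' Reads ASCII STL, ASCII PLY or legacy ASCII VTK polydata. Units are
#' assumed to be mm; no unit inference is attempted. STL files carry no
#' shared vertex indexing, so coincident corners are merged on read
#' (tolerance 1e-6 mm). PLY and VTK files may carry a per-vertex integer
#' `region` property which is decoded to the package's region labels.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"vtk"`; inferred from the file
#'   extension when missing.
#' @return a [surface_mesh()].
#' @export
load_mesh <- function(path, format = infer_mesh_format(path)) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  format <- match.arg(format, c("stl", "ply", "vtk"))
  switch(format,
         stl = read_stl_ascii(path),
         ply = read_ply_ascii(path),
         vtk = read_vtk_polydata(path)$mesh)
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"ply"` or `"vtk"`; inferred from the extension
#'   when missing. STL cannot carry region labels; PLY and VTK store them
#'   as an integer vertex property.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = infer_mesh_format(path)) {
  format <- match.arg(format, c("stl", "ply", "vtk"))
  switch(format,
         stl = write_stl_ascii(mesh, path),
         ply = write_ply_ascii(mesh, path),
         vtk = write_vtk_polydata(mesh, path))
  invisible(path)
}

## ---- STL (ASCII) ----

read_stl_ascii <- function(path) {
  head <- readBin(path, "raw", n = 5L)
  if (!identical(rawToChar(head), "solid")) {
    stop("format error: only ASCII STL is supported (file is not ASCII STL)")
  }
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("format error: no vertices found in STL file")
  if (length(vl) %% 3L != 0L) {
    stop("unsupported topology: STL facet without exactly 3 vertices")
  }
  num <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  if (any(!is.finite(num))) stop("format error: malformed STL vertex line")
  # merge coincident corners (1e-6 mm grid)
  key <- apply(round(num / 1e-6), 1, paste, collapse = " ")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  vertices <- num[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(vertices, faces)
}

write_stl_ascii <- function(mesh, path) {
  fn <- face_normal_vectors(mesh)
  len <- sqrt(rowSums(fn^2))
  len[len == 0] <- 1
  fn <- fn / len
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid blebpoint", con)
  fmt <- function(x) sprintf("%.9g", x)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %s %s %s", fmt(fn[i, 1]), fmt(fn[i, 2]), fmt(fn[i, 3])),
      "    outer loop",
      sprintf("      vertex %s %s %s",
              fmt(v[f[i, ], 1]), fmt(v[f[i, ], 2]), fmt(v[f[i, ], 3])),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid blebpoint", con)
}

## ---- PLY (ASCII) ----

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "ply") {
    stop("format error: not a PLY file")
  }
  if (!grepl("^format ascii", lines[2])) {
    stop("format error: only ASCII PLY is supported")
  }
  end <- match("end_header", lines)
  if (is.na(end)) stop("format error: PLY header not terminated")
  header <- lines[seq_len(end)]
  nv <- nf <- NA_integer_
  vprops <- character()
  in_vertex <- FALSE
  for (h in header) {
    tok <- strsplit(trimws(h), "\\s+")[[1]]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  if (is.na(nv) || is.na(nf)) stop("format error: PLY missing vertex/face elements")
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  fdat <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  counts <- vapply(fdat, function(x) as.integer(x[1]), integer(1))
  if (any(counts != 3L)) {
    stop("unsupported topology: PLY face with ", counts[counts != 3L][1],
         " vertices (triangles required)")
  }
  faces <- do.call(rbind, lapply(fdat, function(x) as.integer(x[2:4]) + 1L))
  region <- NULL
  if ("region" %in% colnames(vdat)) {
    region <- code_to_region(as.integer(vdat[, "region"]))
  }
  surface_mesh(vdat[, c("x", "y", "z")], faces, region = region)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  has_region <- !is.null(mesh$region)
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("ply", "format ascii 1.0",
              "comment written by blebpoint",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              if (has_region) "property int region",
              sprintf("element face %d", nrow(mesh$faces)),
              "property list uchar int vertex_indices",
              "end_header")
  writeLines(header, con)
  if (has_region) {
    writeLines(sprintf("%.9g %.9g %.9g %d", v[, 1], v[, 2], v[, 3],
                       region_to_code(mesh$region)), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  }
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
}

## ---- VTK legacy polydata (ASCII) ----

# Returns list(mesh, point_data) where point_data is a named list of
# per-vertex scalars (numeric vector) and vectors (n x 3 matrix).
read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !grepl("^# vtk DataFile", lines[1])) {
    stop("format error: not a legacy VTK file")
  }
  if (toupper(trimws(lines[3])) != "ASCII") {
    stop("format error: only ASCII VTK is supported")
  }
  if (!grepl("POLYDATA", toupper(lines[4]))) {
    stop("format error: VTK dataset must be POLYDATA")
  }
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- 5L
  vertices <- NULL; faces <- NULL
  point_data <- list()
  n_pd <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    tk <- toks(line)
    kw <- toupper(tk[1])
    if (kw == "POINTS") {
      np <- as.integer(tk[2])
      nums <- numeric(0)
      i <- i + 1L
      while (length(nums) < 3L * np) {
        nums <- c(nums, as.numeric(toks(lines[i])))
        i <- i + 1L
      }
      vertices <- matrix(nums, ncol = 3, byrow = TRUE)
    } else if (kw == "POLYGONS") {
      nf <- as.integer(tk[2])
      ints <- integer(0)
      ntot <- as.integer(tk[3])
      i <- i + 1L
      while (length(ints) < ntot) {
        ints <- c(ints, as.integer(toks(lines[i])))
        i <- i + 1L
      }
      faces <- matrix(NA_integer_, nf, 3)
      p <- 1L
      for (k in seq_len(nf)) {
        cnt <- ints[p]
        if (cnt != 3L) stop("unsupported topology: VTK polygon with ",
                            cnt, " vertices")
        faces[k, ] <- ints[(p + 1L):(p + 3L)] + 1L
        p <- p + cnt + 1L
      }
    } else if (kw == "POINT_DATA") {
      n_pd <- as.integer(tk[2])
      i <- i + 1L
    } else if (kw == "SCALARS") {
      name <- tk[2]
      i <- i + 1L
      if (grepl("^LOOKUP_TABLE", toupper(trimws(lines[i])))) i <- i + 1L
      nums <- numeric(0)
      while (length(nums) < n_pd) {
        nums <- c(nums, as.numeric(toks(lines[i])))
        i <- i + 1L
      }
      point_data[[name]] <- nums
    } else if (kw == "VECTORS") {
      name <- tk[2]
      i <- i + 1L
      nums <- numeric(0)
      while (length(nums) < 3L * n_pd) {
        nums <- c(nums, as.numeric(toks(lines[i])))
        i <- i + 1L
      }
      point_data[[name]] <- matrix(nums, ncol = 3, byrow = TRUE)
    } else {
      i <- i + 1L
    }
  }
  if (is.null(vertices) || is.null(faces)) {
    stop("format error: VTK file lacks POINTS or POLYGONS")
  }
  region <- NULL
  if ("region" %in% names(point_data)) {
    region <- code_to_region(as.integer(point_data$region))
    point_data$region <- NULL
  }
  list(mesh = surface_mesh(vertices, faces, region = region),
       point_data = point_data)
}

write_vtk_polydata <- function(mesh, path, point_data = list()) {
  v <- mesh$vertices
  f0 <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "blebpoint surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f0), 4L * nrow(f0)), con)
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  if (!is.null(mesh$region)) {
    point_data$region <- region_to_code(mesh$region)
  }
  if (length(point_data) > 0L) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (name in names(point_data)) {
      val <- point_data[[name]]
      if (is.matrix(val)) {
        writeLines(sprintf("VECTORS %s double", name), con)
        writeLines(sprintf("%.9g %.9g %.9g", val[, 1], val[, 2], val[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", name),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", val), con)
      }
    }
  }
}

#' Read or write per-vertex region labels as a sidecar CSV
#'
#' The sidecar format is `vertex_id,label` with 1-based vertex ids.
#'
#' @param mesh a [surface_mesh()].
#' @param path CSV path.
#' @return `read_region_labels` returns the mesh with its `region` field
#'   replaced; `write_region_labels` returns `path` invisibly.
#' @export
read_region_labels <- function(mesh, path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_id", "label") %in% names(d))) {
    stop("region sidecar must have columns vertex_id,label")
  }
  region <- rep(NA_character_, n_vertices(mesh))
  if (any(d$vertex_id < 1L | d$vertex_id > n_vertices(mesh))) {
    stop("region sidecar references an invalid vertex id")
  }
  region[d$vertex_id] <- d$label
  surface_mesh(mesh$vertices, mesh$faces, region = region,
               normals = mesh$normals)
}

#' @rdname read_region_labels
#' @export
write_region_labels <- function(mesh, path) {
  if (is.null(mesh$region)) stop("mesh carries no region labels")
  keep <- !is.na(mesh$region)
  utils::write.csv(
    data.frame(vertex_id = which(keep), label = mesh$region[keep]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
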