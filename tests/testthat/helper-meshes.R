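# Flat rectangular patch in the z = 0 plane, triangulated as an nx x ny
# vertex grid (nx = ny = 2 gives the two-triangle square).
flat_patch_mesh <- function(width = 10, height = 10, nx = 2, ny = 2,
                            region = NULL) {
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  v <- cbind(rep(xs, each = ny), rep(ys, nx), 0)
  faces <- matrix(NA_integer_, 2 * (nx - 1) * (ny - 1), 3)
  row <- 1L
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny - 1)) {
      a <- (i - 1) * ny + j
      b <- a + 1L
      c2 <- i * ny + j
      d <- c2 + 1L
      faces[row, ] <- c(a, b, c2); row <- row + 1L
      faces[row, ] <- c(b, d, c2); row <- row + 1L
    }
  }
  surface_mesh(v, faces, region = region)
}

# Interior vertices of a flat grid patch (not on the rectangle border).
grid_interior <- function(mesh) {
  setdiff(seq_len(nrow(mesh$vertices)), boundary_vertices(mesh))
}

# Default synthetic case, built once per test run.
default_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec()
      gen <- make_dome_mesh(spec)
      cache <<- list(spec = spec, mesh = gen$mesh, truth = gen$truth)
    }
    cache
  }
})
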