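#' Primitive meshes
#'
#' Sphere meshes are built by midpoint subdivision of a regular
#' octahedron followed by projection to the unit sphere. Because the
#' octahedron's vertices sit on the coordinate axes, the result is
#' exactly symmetric under negation of any axis — a property the
#' template symmetrization and mirror-pairing code exploits.
#'
#' @param subdivisions number of 1:4 subdivision rounds (level k gives
#'   `8 * 4^k` faces).
#' @param radius sphere radius (mm).
#' @param center 3-vector center.
#' @return a [triangle_mesh()].
#' @export
mesh_sphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  m <- triangle_mesh(v, f, clean = FALSE)
  for (i in seq_len(subdivisions)) {
    m <- subdivide_midpoint(m)
    m$vertices <- normalize_rows(m$vertices)
  }
  m$vertices <- sweep(m$vertices * radius, 2, center, "+")
  m
}

#' Ellipsoid mesh with semi-axes `radii`
#' @param radii 3-vector of semi-axes (mm).
#' @inheritParams mesh_sphere
#' @export
mesh_ellipsoid <- function(radii = c(1, 1, 1), subdivisions = 3,
                           center = c(0, 0, 0)) {
  m <- mesh_sphere(subdivisions)
  m$vertices <- sweep(sweep(m$vertices, 2, radii, "*"), 2, center, "+")
  m
}

#' Axis-aligned unit cube mesh (12 triangles)
#' @param side edge length (mm).
#' @param center 3-vector center.
#' @export
mesh_cube <- function(side = 1, center = c(0, 0, 0)) {
  s <- side / 2
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  # outward-oriented faces of the box
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = -s
             c(5, 8, 7), c(5, 6, 8),   # z = +s
             c(1, 2, 6), c(1, 6, 5),   # y = -s
             c(3, 8, 4), c(3, 7, 8),   # y = +s
             c(1, 7, 3), c(1, 5, 7),   # x = -s
             c(2, 4, 8), c(2, 8, 6))   # x = +s
  m <- triangle_mesh(sweep(v, 2, center, "+"), f, clean = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Flat rectangular grid mesh in the z = 0 plane
#' @param nx,ny vertices along x and y.
#' @param width,height extent in mm.
#' @export
mesh_grid <- function(nx = 10, ny = 10, width = 1, height = 1) {
  xs <- seq(-width / 2, width / 2, length.out = nx)
  ys <- seq(-height / 2, height / 2, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  f <- grid_faces(nx, ny)
  triangle_mesh(v, f, clean = FALSE)
}

grid_faces <- function(nu, nv, wrap_u = FALSE) {
  id <- function(i, j) (j - 1L) * nu + i
  fl <- list()
  imax <- if (wrap_u) nu else nu - 1L
  for (j in seq_len(nv - 1L)) {
    for (i in seq_len(imax)) {
      i2 <- if (wrap_u && i == nu) 1L else i + 1L
      fl[[length(fl) + 1L]] <- rbind(
        c(id(i, j), id(i2, j), id(i2, j + 1L)),
        c(id(i, j), id(i2, j + 1L), id(i, j + 1L)))
    }
  }
  do.call(rbind, fl)
}

#' Midpoint (1:4) subdivision
#'
#' Splits every face into four by inserting edge midpoints; vertex
#' order of the input is preserved at the head of the output.
#' @param mesh a [triangle_mesh()].
#' @export
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(key)
  eid <- match(key, uk)
  ue <- e[match(uk, key), , drop = FALSE]
  mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  midid <- nrow(v) + seq_len(nrow(mid))
  nfc <- nrow(f)
  m12 <- midid[eid[seq_len(nfc)]]
  m23 <- midid[eid[nfc + seq_len(nfc)]]
  m31 <- midid[eid[2 * nfc + seq_len(nfc)]]
  nf <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  triangle_mesh(rbind(v, mid), nf, clean = FALSE)
}
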