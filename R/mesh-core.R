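#' Triangle surface meshes
#'
#' A `triangle_mesh` is the universal geometric substrate of the package:
#' a set of 3D vertices (millimetres) and triangular faces given as
#' 1-based vertex index triples. Construction cleans the mesh: duplicate
#' vertices (within `merge_tol`) are merged and zero-area faces dropped,
#' so downstream code can rely on all faces being non-degenerate.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param merge_tol duplicate-vertex merge tolerance in mm. The default
#'   1e-6 mm is far below scanner precision but above float32 noise.
#' @param clean logical; merge duplicates and drop degenerate faces.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, and `n_dropped_faces` (degenerate faces removed).
#' @examples
#' m <- triangle_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(1:3))
#' mesh_area(m)
#' @export
triangle_mesh <- function(vertices, faces, merge_tol = 1e-6, clean = TRUE) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stopf("faces must be an m x 3 index matrix")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  dimnames(vertices) <- NULL
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stopf("empty mesh: %d vertices, %d faces", nrow(vertices), nrow(faces))
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stopf("face indices out of range [1, %d]", nrow(vertices))

  dropped <- 0L
  if (clean) {
    # merge duplicate vertices within tolerance via rounded-coordinate keys
    key <- apply(round(vertices / max(merge_tol, .Machine$double.eps)), 1,
                 paste, collapse = ",")
    first <- match(key, key)
    if (any(first != seq_along(first))) {
      keep <- sort(unique(first))
      remap <- integer(nrow(vertices))
      remap[keep] <- seq_along(keep)
      faces[] <- remap[first[faces]]
      vertices <- vertices[keep, , drop = FALSE]
    }
    # drop combinatorially or geometrically degenerate faces
    bad <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (!all(bad)) {
      a <- vertices[faces[, 1], , drop = FALSE]
      ar <- tri_areas(a, vertices[faces[, 2], , drop = FALSE],
                      vertices[faces[, 3], , drop = FALSE])
      bad <- bad | ar <= .Machine$double.eps
    }
    dropped <- sum(bad)
    if (dropped == nrow(faces)) stopf("all faces degenerate after cleanup")
    faces <- faces[!bad, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces,
                 n_dropped_faces = dropped),
            class = "triangle_mesh")
}

tri_areas <- function(a, b, c) {
  u <- b - a; v <- c - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  sum(tri_areas(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                v[f[, 3], , drop = FALSE]))
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem volume; positive when faces are consistently
#' oriented outward.
#' @param mesh a `triangle_mesh`
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  vnorm(mesh$vertices[e[, 1], , drop = FALSE] -
        mesh$vertices[e[, 2], , drop = FALSE])
}

# Row-normalized sparse vertex adjacency (with self), used for
# graph-Laplacian smoothing of displacement fields.
mesh_adjacency <- function(mesh, include_self = TRUE) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  i <- c(e[, 1], e[, 2]); j <- c(e[, 2], e[, 1])
  if (include_self) { i <- c(i, seq_len(n)); j <- c(j, seq_len(n)) }
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% a
}

#' Closest point on a mesh surface
#'
#' Exact closest-point query: faces, edges and vertices are all
#' candidates, so the returned distance is the true point-to-surface
#' distance, not a vertex-only approximation.
#'
#' @param mesh a `triangle_mesh`
#' @param p a single 3D point or an n x 3 matrix of query points.
#' @return for a single point, a `surface_point` (list with `position`,
#'   `face_id`, `barycentric`, `distance`); for a matrix, a list with
#'   matrices/vectors `position`, `face_id`, `barycentric`, `distance`.
#' @export
closest_surface_point <- function(mesh, p) {
  single <- is.null(dim(p)) || nrow(as.matrix(p)) == 1L && length(p) == 3L
  q <- if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else as_point_matrix(p, "query points")
  if (!all(is.finite(q))) stopf("query point is non-finite")
  res <- cpp_closest_points(q, mesh$vertices, mesh$faces)
  if (single && nrow(q) == 1L) {
    structure(list(position = drop(res$point[1, ]), face_id = res$face[1],
                   barycentric = drop(res$bary[1, ]), distance = res$distance[1]),
              class = "surface_point")
  } else {
    list(position = res$point, face_id = res$face,
         barycentric = res$bary, distance = res$distance)
  }
}

#' @export
print.surface_point <- function(x, ...) {
  cat(sprintf("surface_point on face %d at (%.4f, %.4f, %.4f), distance %.4g mm\n",
              x$face_id, x$position[1], x$position[2], x$position[3], x$distance))
  invisible(x)
}

#' Angle-weighted per-vertex unit normals
#'
#' Face normals are averaged at each vertex weighted by the incident
#' wedge angle, then normalized. For closed meshes the orientation is
#' made outward using the sign of the enclosed volume.
#'
#' @param mesh a `triangle_mesh`
#' @param outward logical; flip all normals if the mesh encloses
#'   negative signed volume (consistently inward orientation).
#' @return n x 3 matrix of unit normals; isolated vertices get a zero
#'   normal and a warning.
#' @export
vertex_normals <- function(mesh, outward = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  fn <- cbind((b - a)[, 2] * (c_ - a)[, 3] - (b - a)[, 3] * (c_ - a)[, 2],
              (b - a)[, 3] * (c_ - a)[, 1] - (b - a)[, 1] * (c_ - a)[, 3],
              (b - a)[, 1] * (c_ - a)[, 2] - (b - a)[, 2] * (c_ - a)[, 1])
  fn <- normalize_rows(fn)
  corner_angle <- function(p, q, r) {
    u <- normalize_rows(q - p); w <- normalize_rows(r - p)
    acos(pmin(1, pmax(-1, rowSums(u * w))))
  }
  ang <- cbind(corner_angle(a, b, c_), corner_angle(b, c_, a),
               corner_angle(c_, a, b))
  for (k in 1:3) {
    w <- ang[, k] * fn
    for (d in 1:3)
      n[, d] <- n[, d] + tapply_add(w[, d], f[, k], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  iso <- len == 0
  if (any(iso)) warning(sprintf("%d isolated vertices have zero normals", sum(iso)))
  len[iso] <- 1
  n <- n / len
  if (outward && abs(mesh_volume(mesh)) > .Machine$double.eps &&
      mesh_volume(mesh) < 0) n <- -n
  n
}

face_unit_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  normalize_rows(cbind(
    (b - a)[, 2] * (c_ - a)[, 3] - (b - a)[, 3] * (c_ - a)[, 2],
    (b - a)[, 3] * (c_ - a)[, 1] - (b - a)[, 1] * (c_ - a)[, 3],
    (b - a)[, 1] * (c_ - a)[, 2] - (b - a)[, 2] * (c_ - a)[, 1]))
}

# flat CSR-like neighbour structure (neighbours + self) for diffusion
mesh_neighbours <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  i <- c(e[, 1], e[, 2], seq_len(n))
  j <- c(e[, 2], e[, 1], seq_len(n))
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  counts <- tabulate(i, nbins = n)
  list(offs = c(0L, cumsum(counts)), nbr = as.integer(j))
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
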