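test_that("mesh construction cleans duplicates and degenerate faces", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)

  # a zero-area face (three collinear vertices) is dropped and counted
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face collinear
  m2 <- triangle_mesh(v, f)
  expect_equal(nrow(m2$faces), 1L)
  expect_equal(m2$n_dropped_faces, 1L)

  # duplicate vertices within 1e-6 mm are merged
  v3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-9, 0, 0))
  m3 <- triangle_mesh(v3, rbind(c(4, 2, 3)))
  expect_equal(nrow(m3$vertices), 3L)

  expect_error(triangle_mesh(matrix(numeric(), 0, 3), rbind(1:3)), "empty")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 5))), "out of range")
})

test_that("mesh I/O round-trips through OBJ, PLY and STL", {
  s <- mesh_sphere(2, radius = 13.7, center = c(1, -2, 3))
  for (ext in c("obj", "ply")) {
    tf <- tempfile(fileext = paste0(".", ext))
    write_mesh(s, tf)
    s2 <- read_mesh(tf)
    expect_lt(max(abs(s2$vertices - s$vertices)), 1e-6)
    expect_identical(s2$faces, s$faces)
  }
  # OBJ write-read-write is byte-identical (idempotent geometry section)
  t1 <- tempfile(fileext = ".obj"); t2 <- tempfile(fileext = ".obj")
  write_mesh(s, t1)
  write_mesh(read_mesh(t1), t2)
  expect_identical(readLines(t1), readLines(t2))

  # STL loses shared vertices but preserves the surface
  for (bin in c(FALSE, TRUE)) {
    tf <- tempfile(fileext = ".stl")
    write_mesh(s, tf, binary = bin)
    s3 <- read_mesh(tf)
    expect_lt(abs(mesh_area(s3) - mesh_area(s)) / mesh_area(s), 1e-5)
  }

  # 20-vertex landmark files round-trip in CSV and JSON
  lm <- random_landmarks(20, seed = 3)
  for (ext in c("csv", "json")) {
    tf <- tempfile(fileext = paste0(".", ext))
    write_landmarks(lm, tf)
    lm2 <- read_landmarks(tf)
    expect_equal(lm2$names, lm$names)
    expect_lt(max(abs(lm2$points - lm$points)), 1e-8)
  }

  expect_error(read_mesh(tempfile(fileext = ".obj")), "exist")
  bad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0"), bad)
  expect_error(read_mesh(bad), "face")
})

test_that("closest_surface_point is exact against a brute-force oracle", {
  m <- mesh_ellipsoid(c(3, 2, 1.5), subdivisions = 2)
  # vertex query: distance 0, barycentric a permutation of (1,0,0)
  sp <- closest_surface_point(m, m$vertices[5, ])
  expect_lt(sp$distance, 1e-12)
  expect_equal(sort(sp$barycentric), c(0, 0, 1), tolerance = 1e-9)

  # orthogonal projection onto a flat triangle
  flat <- triangle_mesh(rbind(c(-1, -1, 0), c(2, -1, 0), c(-1, 2, 0)),
                        rbind(1:3))
  sp2 <- closest_surface_point(flat, c(0, 0, 2))
  expect_equal(unname(sp2$position), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sp2$distance, 2)

  set.seed(42)
  for (i in 1:8) {
    p <- rnorm(3, sd = 2.5)
    sp <- closest_surface_point(m, p)
    bf <- brute_closest(m, p)
    expect_lt(abs(sp$distance - bf$distance), 1e-9)
    # the surface distance never exceeds the best vertex distance
    expect_lte(sp$distance, min(sqrt(colSums((t(m$vertices) - p)^2))) + 1e-12)
  }
})

test_that("vertex normals are radial on a sphere and outward on convex bodies", {
  s <- mesh_sphere(3, radius = 2)
  n <- vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  ang <- acos(pmin(1, rowSums(n * radial))) * 180 / pi
  expect_lt(max(ang), 2)

  g <- mesh_grid(5, 5)
  ng <- vertex_normals(g, outward = FALSE)
  expect_true(all(abs(abs(ng[, 3]) - 1) < 1e-12))
  expect_equal(length(unique(sign(ng[, 3]))), 1L)

  cube <- mesh_cube(2)
  nc <- vertex_normals(cube)
  ctr <- colMeans(cube$vertices)
  expect_true(all(rowSums(nc * sweep(cube$vertices, 2, ctr)) > 0))

  # normals are invariant under uniform scaling
  s2 <- s; s2$vertices <- s$vertices * 7.3
  expect_equal(vertex_normals(s2), n, tolerance = 1e-12)
})

test_that("area and volume match closed forms on analytic bodies", {
  s <- mesh_sphere(4, radius = 3)
  expect_lt(abs(mesh_area(s) - 4 * pi * 9) / (4 * pi * 9), 0.01)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.01)
  expect_equal(mesh_volume(mesh_cube(2)), 8, tolerance = 1e-12)
})
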