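test_that("similarity_from_landmarks recovers exact transforms", {
  lm <- random_landmarks(11, seed = 2)
  # identity
  tr0 <- similarity_from_landmarks(lm, lm)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr0$scale, 1, tolerance = 1e-12)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(tr0, "rms"), 1e-12)

  # known rotation + scale + translation recovered to machine precision
  R <- rotation_z(30)
  tru <- similarity_transform(R, c(5, -3, 2), 2)
  lm2 <- landmark_config(apply_transform(tru, lm$points), lm$names)
  tr <- similarity_from_landmarks(lm, lm2)
  expect_lt(max(abs(tr$rotation - R)), 1e-9)
  expect_lt(abs(tr$scale - 2), 1e-9)
  expect_lt(max(abs(tr$translation - c(5, -3, 2))), 1e-9)
  expect_lt(attr(tr, "rms"), 1e-9)

  # residual RMS under known noise stays in the expected band
  set.seed(99)
  rms <- replicate(100, {
    noisy <- landmark_config(lm2$points + matrix(rnorm(33, sd = 0.5), ncol = 3),
                             lm$names)
    attr(similarity_from_landmarks(lm, noisy), "rms")
  })
  expect_true(mean(rms) > 0.2 && mean(rms) < 1.0)

  # error cases: too few, collinear, name mismatch
  two <- landmark_config(lm$points[1:2, ], lm$names[1:2])
  expect_error(similarity_from_landmarks(two, two), "3 landmarks")
  col <- landmark_config(cbind(1:5, 2 * (1:5), 3 * (1:5)), letters[1:5])
  expect_error(similarity_from_landmarks(col, col), "collinear")
  ren <- landmark_config(lm$points, paste0("x", lm$names))
  expect_error(similarity_from_landmarks(lm, ren), "names differ")
})

test_that("rigid ICP holds exact overlap and converges from a perturbed start", {
  m <- mesh_ellipsoid(c(30, 40, 25), subdivisions = 3)
  tru <- similarity_transform(rotation_z(30), c(5, -3, 2), 2)
  tgt <- apply_transform(tru, m)

  # exact-overlap fixed point: starting at the truth stays at the truth
  icp0 <- rigid_icp(m, tgt, tru, max_iter = 10)
  expect_lt(attr(icp0, "rms"), 1e-9)
  expect_lt(max(abs(icp0$rotation - tru$rotation)), 1e-9)

  # 5 degree / 5 mm / 10% scale perturbation converges back
  init <- similarity_transform(rotation_z(25), c(3, -1, 0), 1.8)
  icp <- rigid_icp(m, tgt, init, max_iter = 400)
  expect_lt(attr(icp, "rms"), 0.1)

  # partial target (posterior 30% removed) still converges via trimming
  zc <- (tgt$vertices[tgt$faces[, 1], 3] + tgt$vertices[tgt$faces[, 2], 3] +
           tgt$vertices[tgt$faces[, 3], 3]) / 3
  part <- triangle_mesh(tgt$vertices, tgt$faces[zc > quantile(zc, 0.3), ])
  icp2 <- rigid_icp(m, part, tru, max_iter = 50)
  expect_lt(attr(icp2, "rms"), 0.5)

  # a hopeless initialization is rejected
  far <- similarity_transform(diag(3), c(1e4, 0, 0), 1)
  expect_error(rigid_icp(m, tgt, far), "initial alignment")
})

test_that("non-rigid registration is a fixed point on itself and recovers deformation", {
  pop <- generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, deformation_amplitude = 5,
    asymmetry_sd = 1, vertex_noise = 0, pose_rotation_sd = 0,
    pose_translation_sd = 0, size_sd = 0, seed = 21))
  base <- pop$base

  # target = mask: output equals the mask almost exactly
  ms0 <- nonrigid_register(base, base,
                           nonrigid_config(num_iterations = 10,
                                           stiffness_start = 10,
                                           stiffness_end = 2))
  expect_lt(max(abs(ms0$quasi - base$vertices)), 1e-6)
  expect_equal(nrow(ms0$quasi), nrow(base$vertices))

  # known smooth deformation, same frame: sub-mm mean recovery
  ind <- pop$individuals[[1]]
  ms <- nonrigid_register(base, ind$mesh, nonrigid_config())
  err <- sqrt(rowSums((ms$quasi - ind$truth_quasi$quasi)^2))
  expect_lt(mean(err), 1.0)

  # target with a hole: interpolated smoothly, finite, bounded stretch
  keep <- sqrt(colSums((t(ind$mesh$vertices[ind$mesh$faces[, 1], ]) -
                          c(0, 0, 80))^2)) > 10
  holed <- triangle_mesh(ind$mesh$vertices, ind$mesh$faces[keep, ])
  msh <- nonrigid_register(base, holed, nonrigid_config())
  expect_true(all(is.finite(msh$quasi)))
  el0 <- edge_lengths(base)
  el1 <- edge_lengths(as_mesh(msh))
  expect_lt(max(el1 / el0), 3)
})

test_that("registration is equivariant under rigid motion of the target", {
  pop <- generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, pose_rotation_sd = 0,
    pose_translation_sd = 0, size_sd = 0, vertex_noise = 0, seed = 31))
  base <- pop$base
  ind <- pop$individuals[[1]]
  ids <- pop$landmark_ids
  mask_lm <- landmark_config(base$vertices[ids, ], names(ids))
  tgt_lm <- ind$truth_landmarks
  cfg <- nonrigid_config(num_iterations = 20, stiffness_start = 20,
                         stiffness_end = 2)
  reg1 <- register_mask(base, ind$mesh, mask_lm, tgt_lm, cfg = cfg)

  mot <- similarity_transform(rotation_z(40), c(12, -7, 30), 1)
  tgt2 <- apply_transform(mot, ind$mesh)
  lm2 <- apply_transform(mot, tgt_lm)
  reg2 <- register_mask(base, tgt2, mask_lm, lm2, cfg = cfg)

  back <- apply_transform(mot, reg1$masked$quasi)
  expect_lt(mean(vnorm(reg2$masked$quasi - back)), 1e-4)
})

test_that("qc overlay writes distance statistics deterministically", {
  m <- mesh_sphere(2, radius = 10)
  ms <- masked_shape(m$vertices + 2, m$faces)  # uniform 2 mm shift
  png_path <- tempfile(fileext = ".png")
  jp <- suppressWarnings(qc_overlay(ms, m, png_path))
  expect_true(file.exists(jp))
  st <- jsonlite::read_json(jp, simplifyVector = TRUE)
  # shifted mask: distances concentrate near the shift magnitude scale
  expect_gt(st$median, 0.3)
  jp2 <- suppressWarnings(qc_overlay(ms, m, tempfile(fileext = ".png")))
  expect_identical(jsonlite::read_json(jp, simplifyVector = TRUE)$mean,
                   jsonlite::read_json(jp2, simplifyVector = TRUE)$mean)
})

test_that("closest-point correspondence mode also adapts the template", {
  pop <- generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, deformation_amplitude = 3,
    asymmetry_sd = 0.5, vertex_noise = 0, pose_rotation_sd = 0,
    pose_translation_sd = 0, size_sd = 0, seed = 51))
  base <- pop$base
  ind <- pop$individuals[[1]]
  ms <- nonrigid_register(base, ind$mesh,
                          nonrigid_config(correspondence = "closest"))
  d <- cpp_closest_points(ms$quasi, ind$mesh$vertices,
                          ind$mesh$faces)$distance
  # the surface is matched (to a looser tolerance than normal mode:
  # robustly trimmed closest-point pulls converge more conservatively)
  expect_lt(mean(d), 1.5)
  expect_equal(nrow(ms$quasi), nrow(base$vertices))
})

test_that("the command-line dispatcher runs the simulate subcommand", {
  out <- file.path(tempdir(), "cli_sim")
  code <- densecranio_cli(c("simulate", "--out", out, "--n", "2",
                            "--seed", "4"))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "skull01.ply")))
  expect_true(file.exists(file.path(out, "template_landmarks.csv")))
  expect_equal(suppressMessages(densecranio_cli(character())), 2L)
})
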