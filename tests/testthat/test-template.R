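test_that("GPA aligns identical, rotated and noisy shapes correctly", {
  set.seed(7)
  q <- matrix(rnorm(30 * 3, sd = 10), ncol = 3)

  # identical shapes: consensus equals input, residuals zero
  g0 <- gpa(list(q, q, q), with_scaling = TRUE)
  qc <- sweep(q, 2, colMeans(q))
  expect_lt(max(abs(g0$mean - qc)), 1e-8)
  expect_lt(procrustes_distance(g0$aligned[[1]], g0$aligned[[2]]), 1e-12)

  # rotation + scale is removed entirely
  q2 <- 2 * q %*% t(rotation_z(55)) + 5
  expect_lt(procrustes_distance(q, q2), 1e-9)

  # CLT-scale recovery: mean of noisy copies approaches the template
  sigma <- 0.5
  shapes <- lapply(1:10, function(i) q + matrix(rnorm(90, sd = sigma), ncol = 3))
  g <- gpa(shapes, with_scaling = FALSE)
  expect_lt(max(abs(g$mean - qc)), sigma / sqrt(10) * 5)

  # consensus is invariant to input order
  g_perm <- gpa(shapes[c(4, 9, 1, 7, 2, 10, 3, 6, 5, 8)], with_scaling = FALSE)
  expect_lt(max(abs(g$mean - g_perm$mean)), 1e-9)

  # centroid sizes match the direct formula
  cs_direct <- vapply(shapes, function(m)
    sqrt(sum(sweep(m, 2, colMeans(m))^2)), 0)
  expect_equal(g$centroid_sizes, cs_direct, tolerance = 1e-12)

  expect_error(gpa(list(q, q[1:10, ])), "same number")
})

test_that("plane symmetrization produces exact mirror symmetry", {
  s <- mesh_sphere(3, radius = 10)
  sym <- plane_symmetrize(s, tol = 1e-6)
  p <- mirror_pairing(sym)
  expect_true(all(p[p] == seq_along(p)))

  # perturb one side: output halves are exact mirror images
  s2 <- s
  right <- s2$vertices[, 1] > 0.5
  s2$vertices[right, ] <- s2$vertices[right, ] * 1.07
  sym2 <- plane_symmetrize(s2, tol = 0.05)
  vm <- sym2$vertices %*% diag(c(-1, 1, 1))
  nn <- cpp_nearest_vertex(vm, sym2$vertices)
  expect_lt(max(nn$distance), 1e-9)

  # near-plane vertex snapping
  g <- mesh_grid(5, 5, width = 2, height = 2)
  g$vertices[, 1] <- g$vertices[, 1] + 0.01
  symg <- plane_symmetrize(g, tol = 0.1)
  expect_true(any(symg$vertices[, 1] == 0))
})

test_that("reflection averaging symmetrizes exactly", {
  s <- mesh_sphere(2, radius = 10)
  pairing <- mirror_pairing(s)

  # already symmetric shape is a fixed point
  out <- reflection_average(s$vertices, pairing)
  expect_lt(max(abs(out - s$vertices)), 1e-9)

  # displacing one side by +2 mm ends up +1 mm on both sides
  v2 <- s$vertices
  side <- v2[, 1] > 0.1
  v2[side, 3] <- v2[side, 3] + 2
  avg <- reflection_average(v2, pairing)
  expect_lt(asymmetry_score(avg, pairing), 1e-9)

  # arbitrary perturbation: asymmetry of the output is numerically zero
  set.seed(3)
  v3 <- s$vertices + matrix(rnorm(length(s$vertices), sd = 0.5), ncol = 3)
  avg3 <- reflection_average(v3, pairing)
  expect_lt(asymmetry_score(avg3, pairing), 1e-9)

  expect_error(reflection_average(v3, c(2, 3, 1, seq(4, nrow(v3)))),
               "involution")
})

test_that("build_template averages registered individuals toward the base", {
  spec <- population_spec(n_individuals = 5, subdivisions = 3,
                          deformation_amplitude = 3, asymmetry_sd = 0.5,
                          pose_rotation_sd = 2, pose_translation_sd = 3,
                          size_sd = 0.01, vertex_noise = 0, seed = 11)
  pop <- generate_population(spec)
  base <- pop$base
  ids <- pop$landmark_ids
  mask_lm <- landmark_config(base$vertices[ids, ], names(ids))
  cfg <- nonrigid_config(num_iterations = 20, stiffness_start = 20,
                         stiffness_end = 2)

  templ <- build_template(lapply(pop$individuals, `[[`, "mesh"), base,
                          mask_lm,
                          lapply(pop$individuals, `[[`, "truth_landmarks"),
                          cfg = cfg)
  expect_equal(nrow(templ$vertices), nrow(base$vertices))
  pairing <- attr(templ, "pairing")
  expect_lt(asymmetry_score(templ$vertices, pairing), 1e-6)

  # averaging reduces distance to the base below the typical individual
  d_templ <- procrustes_distance(templ$vertices, base$vertices)
  d_ind <- mean(vapply(pop$individuals, function(ind)
    procrustes_distance(ind$truth_quasi$quasi, base$vertices), 0))
  expect_lt(d_templ, d_ind)
})
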