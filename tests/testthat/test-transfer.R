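test_that("barycentric encode/decode is exact in-plane", {
  set.seed(5)
  q <- matrix(rnorm(60, sd = 10), ncol = 3)
  masked <- masked_shape(q, rbind(1:3))

  # a landmark sitting exactly on a quasi-landmark gets weight 1 there
  anc <- encode_barycentric(q[7, ], masked)
  expect_true(7 %in% anc$quasi_ids)
  expect_equal(anc$weights[anc$quasi_ids == 7], 1, tolerance = 1e-9)

  # centroid of the three nearest points: equal thirds
  three <- masked_shape(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(50, 50, 50)), rbind(1:3))
  ctr <- c(1 / 3, 1 / 3, 0)
  anc2 <- encode_barycentric(ctr, three)
  expect_equal(sort(anc2$quasi_ids), 1:3)
  expect_equal(anc2$weights[order(anc2$quasi_ids)], rep(1 / 3, 3),
               tolerance = 1e-9)

  # decode is plain arithmetic, extrapolation allowed
  a3 <- barycentric_anchor(1:3, c(-1, 1, 1))
  pts <- masked_shape(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), rbind(1:3))
  expect_equal(decode_barycentric(a3, pts), c(-1, 1, 1), tolerance = 1e-12)
  expect_equal(decode_barycentric(barycentric_anchor(1:3, c(0.5, 0.5, 0)),
                                  masked_shape(rbind(c(0, 0, 0), c(2, 0, 0),
                                                     c(9, 9, 9)), rbind(1:3))),
               c(1, 0, 0))

  # round trip: decode(encode(p)) reproduces the in-plane projection
  for (i in 1:10) {
    p <- rnorm(3, sd = 10)
    anc <- encode_barycentric(p, masked)
    dec <- decode_barycentric(anc, masked)
    tri <- q[anc$quasi_ids, ]
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    n <- n / sqrt(sum(n^2))
    proj <- p - n * sum(n * (p - tri[1, ]))
    expect_lt(max(abs(dec - proj)), 1e-9)
  }

  expect_error(encode_barycentric(c(NA, 0, 0), masked), "finite")
  expect_error(decode_barycentric(barycentric_anchor(c(1, 2, 999),
                                                     c(1, 0, 0)), masked),
               "range")
  expect_error(barycentric_anchor(1:3, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("landmark transfer projects onto the target surface and is equivariant", {
  pop <- generate_population(population_spec(
    n_individuals = 3, subdivisions = 3, deformation_amplitude = 2,
    asymmetry_sd = 0.3, pose_rotation_sd = 0, pose_translation_sd = 0,
    size_sd = 0.01, vertex_noise = 0, seed = 13))
  shapes <- lapply(pop$individuals, function(ind)
    list(masked = ind$truth_quasi, landmarks = ind$truth_landmarks,
         mesh = ind$mesh))

  # self-transfer returns the landmark's own surface projection
  auto <- transfer_landmarks(list(shapes[[1]]), shapes[[1]]$masked,
                             shapes[[1]]$mesh)
  d <- vnorm(auto$points - shapes[[1]]$landmarks$points)
  expect_lt(max(d), 1e-9)

  # output always lies on the target surface even when the average
  # decodes off-surface
  auto2 <- transfer_landmarks(shapes[1:2], shapes[[3]]$masked, shapes[[3]]$mesh)
  don <- vapply(seq_len(nrow(auto2$points)), function(i)
    closest_surface_point(shapes[[3]]$mesh, auto2$points[i, ])$distance, 0)
  expect_lt(max(don), 1e-9)

  # rigid equivariance: transforming target + masked transforms output
  mot <- similarity_transform(rotation_z(25), c(3, 4, -5), 1)
  masked_t <- shapes[[3]]$masked
  masked_t$quasi <- apply_transform(mot, masked_t$quasi)
  auto3 <- transfer_landmarks(shapes[1:2], masked_t,
                              apply_transform(mot, shapes[[3]]$mesh))
  expect_lt(max(vnorm(auto3$points - apply_transform(mot, auto2$points))),
            1e-6)

  # mismatched names fail loudly
  bad <- shapes[1:2]
  bad[[2]]$landmarks <- landmark_config(bad[[2]]$landmarks$points,
                                        paste0("zz", bad[[2]]$landmarks$names))
  expect_error(transfer_landmarks(bad, shapes[[3]]$masked, shapes[[3]]$mesh),
               "names differ")
})

test_that("leave-one-out errors are zero in a noise-free world and shrink with training size", {
  pop <- generate_population(population_spec(
    n_individuals = 6, subdivisions = 3, deformation_amplitude = 2,
    asymmetry_sd = 0.3, vertex_noise = 0, seed = 17))
  # perfect registration + noise-free observers: all errors vanish
  inp <- lapply(pop$individuals, function(ind)
    list(masked = ind$truth_quasi, mesh = ind$mesh,
         landmarks = list(mean = ind$truth_landmarks)))
  res <- loo_evaluate(inp)
  expect_lt(max(res$errors$distance), 1e-9)
  expect_true(all(res$errors$distance >= 0))
  expect_equal(res$mean, mean(res$errors$distance[res$errors$observer == "mean"]))

  # with iid landmark noise, more training shapes help (on average)
  set.seed(23)
  noisy_lms <- lapply(pop$individuals, function(ind) {
    pts <- ind$truth_landmarks$points + matrix(rnorm(60, sd = 1), ncol = 3)
    landmark_config(pts, ind$truth_landmarks$names)
  })
  err_for_train <- function(n_train) {
    tr <- lapply(seq_len(n_train), function(i)
      list(masked = pop$individuals[[i]]$truth_quasi,
           landmarks = noisy_lms[[i]]))
    auto <- transfer_landmarks(tr, pop$individuals[[6]]$truth_quasi,
                               pop$individuals[[6]]$mesh)
    mean(vnorm(auto$points - pop$individuals[[6]]$truth_landmarks$points))
  }
  expect_lt(err_for_train(5), err_for_train(1) + 0.2)
  expect_error(loo_evaluate(inp[1:2]), "at least 3")
})
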