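test_that("population generation is deterministic and respects its dials", {
  spec <- population_spec(n_individuals = 3, subdivisions = 3, seed = 5)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1$individuals[[2]]$mesh$vertices,
                   p2$individuals[[2]]$mesh$vertices)
  expect_identical(p1$individuals[[3]]$truth_landmarks$points,
                   p2$individuals[[3]]$truth_landmarks$points)

  # zero amplitude, zero pose/size variation: individuals equal the base
  flat <- generate_population(population_spec(
    n_individuals = 2, subdivisions = 3, deformation_amplitude = 0,
    asymmetry_sd = 0, size_sd = 0, pose_rotation_sd = 0,
    pose_translation_sd = 0, vertex_noise = 0, seed = 5))
  expect_lt(max(abs(flat$individuals[[1]]$mesh$vertices -
                      flat$base$vertices)), 1e-9)

  # deformation scale: mean displacement RMS tracks the amplitude
  amp <- 5
  pop <- generate_population(population_spec(
    n_individuals = 8, subdivisions = 3, deformation_amplitude = amp,
    asymmetry_sd = 0, size_sd = 0, pose_rotation_sd = 0,
    pose_translation_sd = 0, vertex_noise = 0, seed = 9))
  disp <- vapply(pop$individuals, function(ind)
    sqrt(mean(rowSums((ind$truth_quasi$quasi - pop$base$vertices)^2))), 0)
  expect_gt(mean(disp), amp / 2)
  expect_lt(mean(disp), amp * 2)

  # pairwise Procrustes distances are on the expected scale too
  pd <- procrustes_distance(pop$individuals[[1]]$truth_quasi,
                            pop$individuals[[2]]$truth_quasi,
                            with_scaling = FALSE)
  expect_gt(pd, amp / 4)
  expect_lt(pd, amp * 2)

  # truncation drops posterior faces but must never delete a landmark
  tr <- generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, truncation_fraction = 0.2, seed = 5))
  expect_lt(nrow(tr$individuals[[1]]$mesh$faces), nrow(tr$base$faces))
  expect_error(generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, truncation_fraction = 0.85,
    seed = 5)), "landmark")
})

test_that("simulated observers reproduce the intra/inter error structure", {
  pop <- generate_population(population_spec(
    n_individuals = 6, subdivisions = 3, seed = 7))

  # noise-free, bias-free observers reproduce the truth
  clean <- simulate_observers(pop, observer_spec(
    noise_sd = c(0, 0), bias_amplitude = c(0, 0), seed = 3))
  expect_lt(max(abs(clean$landmarks[2, 1, 1, , ] -
                      pop$individuals[[2]]$truth_landmarks$points)), 1e-6)

  # same seed is byte-identical
  s1 <- simulate_observers(pop, observer_spec(seed = 11))
  s2 <- simulate_observers(pop, observer_spec(seed = 11))
  expect_identical(s1$landmarks, s2$landmarks)

  # intra-observer RMS tracks sigma * sqrt(3 (R-1)/R) reduced by the
  # on-surface projection (normal component removed)
  sigma <- 0.8
  st <- simulate_observers(pop, observer_spec(
    noise_sd = rep(sigma, 2), bias_amplitude = c(0, 0), seed = 13))
  intra <- mean(vapply(1:6, function(s)
    rms_repeat(lapply(1:3, function(r) st$landmarks[s, 1, r, , ]))$mean, 0))
  expect_gt(intra, sigma * sqrt(2) * 0.6)
  expect_lt(intra, sigma * sqrt(2) * 1.1)

  # equal noise but different bias fields: inter exceeds intra
  st2 <- simulate_observers(pop, observer_spec(
    noise_sd = c(0.5, 0.5), bias_amplitude = c(1.2, 1.2), seed = 17))
  intra2 <- mean(vapply(1:6, function(s)
    rms_repeat(lapply(1:3, function(r) st2$landmarks[s, 1, r, , ]))$mean, 0))
  inter2 <- mean(vapply(1:6, function(s)
    rms_between(list(observer_mean_config(st2, s, 1)$points,
                     observer_mean_config(st2, s, 2)$points))$mean, 0))
  expect_gt(inter2, intra2)
})

test_that("generated surfaces are exactly mirror-symmetric at zero asymmetry", {
  pop <- generate_population(population_spec(
    n_individuals = 1, subdivisions = 3, asymmetry_sd = 0,
    pose_rotation_sd = 0, pose_translation_sd = 0, size_sd = 0,
    vertex_noise = 0, seed = 19))
  pairing <- mirror_pairing(pop$base)
  expect_lt(asymmetry_score(pop$individuals[[1]]$truth_quasi$quasi, pairing),
            0.05)
})
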