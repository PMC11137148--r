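#' Synthetic skull-like surfaces with known ground truth
#'
#' The generator emulates a cone-beam-CT skull cohort at desk scale:
#' a closed, bilaterally symmetric base surface (an ellipsoid decorated
#' with zygomatic, orbital, nasal, brow and jaw features) is deformed
#' per individual by a smooth random radial-basis displacement field of
#' controlled amplitude and wavelength, optionally truncated
#' posteriorly and punctured (field-of-view artifacts). Because every
#' individual is a deformation of the same base mesh, ground-truth
#' dense correspondence and landmark positions are known exactly,
#' which is what makes registration and transfer errors measurable.
#'
#' @name synthetic
NULL

# feature bumps: (unit direction, amplitude mm, kernel sd mm, optional
# ring radius mm for annular features); entries with x != 0 are applied
# together with their mirror image. Amplitudes are deliberately strong:
# the orbital rims, nasal aperture, tooth row and jaw angles are what
# make the pose of a real skull geometrically identifiable, and the
# synthetic analog needs the same property.
skull_features <- function() {
  list(
    list(dir = c(0.00, -0.02, 1.00), amp = 16, sd = 9, name = "nasal ridge"),
    list(dir = c(0.00, -0.18, 1.00), amp = -10, sd = 6, name = "nasal aperture"),
    list(dir = c(0.00, -0.45, 0.90), amp = 10, sd = 8, name = "mouth"),
    list(dir = c(0.00, -0.80, 0.60), amp = 12, sd = 9, name = "chin"),
    list(dir = c(0.50, 0.12, 0.85), amp = -12, sd = 8, name = "orbit"),
    list(dir = c(0.50, 0.12, 0.85), amp = 8, sd = 5, ring = 12, name = "orbital rim"),
    list(dir = c(0.80, 0.02, 0.55), amp = 14, sd = 9, name = "zygomatic"),
    list(dir = c(0.45, 0.42, 0.80), amp = 9, sd = 8, name = "brow"),
    list(dir = c(0.95, -0.30, 0.10), amp = 12, sd = 10, name = "gonial"),
    list(dir = c(0.30, -0.60, 0.72), amp = -7, sd = 6, name = "cheek hollow"),
    list(dir = c(0.15, 0.75, 0.40), amp = 7, sd = 10, name = "frontal"),
    list(dir = c(0.60, -0.55, 0.45), amp = 9, sd = 7, name = "mandible"),
    list(dir = c(0.10, -0.42, 0.98), amp = 7, sd = 4, name = "canine"),
    list(dir = c(0.28, -0.38, 0.92), amp = 7, sd = 4, name = "molar"),
    list(dir = c(0.70, 0.30, 0.60), amp = -6, sd = 5, name = "temporal fossa")
  )
}

#' Base skull-like surface
#'
#' Exactly mirror-symmetric about x = 0. Dimensions are adult-skull
#' scale (roughly 120 x 170 x 140 mm); the nose points along +z, the
#' vertical axis is y, the posterior is -z.
#'
#' @param subdivisions sphere subdivision level (level k: `8*4^k` faces).
#' @return a [triangle_mesh()].
#' @export
base_skull_mesh <- function(subdivisions = 4) {
  radii <- c(60, 85, 70)
  m <- mesh_sphere(subdivisions)
  u <- m$vertices  # unit sphere positions
  v <- sweep(u, 2, radii, "*")
  bump <- numeric(nrow(v))
  for (ft in skull_features()) {
    ctrs <- list(ft$dir / sqrt(sum(ft$dir^2)))
    if (abs(ft$dir[1]) > 1e-12)
      ctrs[[2]] <- ctrs[[1]] * c(-1, 1, 1)
    for (ctr in ctrs) {
      cpos <- ctr * radii
      d <- sqrt(rowSums(sweep(v, 2, cpos)^2))
      r0 <- ft$ring %||% 0
      bump <- bump + ft$amp * exp(-(d - r0)^2 / (2 * ft$sd^2))
    }
  }
  m$vertices <- v + u * bump  # radial displacement keeps symmetry
  m
}

#' Population specification for the synthetic generator
#'
#' Defaults are the package's reference study conditions: 10
#' individuals, smooth deformation of 5 mm RMS amplitude and 60 mm
#' wavelength, 1 mm asymmetry, 3% global size variation, no
#' truncation or holes and no target vertex noise.
#'
#' @param n_individuals number of skulls.
#' @param deformation_amplitude RMS displacement of the per-individual
#'   smooth field (mm).
#' @param deformation_smoothness spatial wavelength of the field (mm);
#'   the radial-basis kernel sd is a quarter wavelength.
#' @param asymmetry_sd RMS of the antisymmetric field component (mm).
#' @param size_sd sd of the global per-individual size factor.
#' @param truncation_fraction fraction of faces removed from the
#'   posterior of each target mesh (`[0, 1)`).
#' @param hole_spec list of `list(dir = unit direction, radius = mm)`
#'   holes punched into each target mesh.
#' @param vertex_noise iid Gaussian jitter sd (mm) added to target mesh
#'   vertices (the ground truth stays noise-free).
#' @param pose_rotation_sd,pose_translation_sd random rigid pose per
#'   individual (degrees / mm).
#' @param n_bumps radial-basis bumps per field.
#' @param subdivisions mesh resolution of the base surface.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @export
population_spec <- function(n_individuals = 10, deformation_amplitude = 5,
                            deformation_smoothness = 60, asymmetry_sd = 1,
                            size_sd = 0.03, truncation_fraction = 0,
                            hole_spec = NULL, vertex_noise = 0,
                            pose_rotation_sd = 5, pose_translation_sd = 10,
                            n_bumps = 30, subdivisions = 4, seed = 1) {
  stopifnot(n_individuals >= 1, deformation_amplitude >= 0, asymmetry_sd >= 0,
            truncation_fraction >= 0, truncation_fraction < 1, vertex_noise >= 0)
  structure(as.list(environment()), class = "population_spec")
}

# 20 validation landmarks as approximate unit directions on the base;
# midline landmarks have x = 0, paired ones are mirrored automatically.
validation_landmark_dirs <- function() {
  mid <- list(Nasion = c(0, 0.12, 1), Subspinale = c(0, -0.30, 1),
              Incision = c(0, -0.52, 0.95), Pogonion = c(0, -0.80, 0.62))
  pair <- list("Frontomalare Orbital" = c(0.60, 0.22, 0.77),
               "Orbitale" = c(0.42, 0.02, 0.92),
               "Zygomaxillare" = c(0.48, -0.18, 0.86),
               "Intercanine" = c(0.12, -0.50, 0.95),
               "Marginal Tubercle" = c(0.72, 0.22, 0.62),
               "Zygion" = c(0.92, 0.05, 0.38),
               "Koronion" = c(0.88, -0.12, 0.45),
               "Gonion" = c(0.92, -0.35, 0.12))
  out <- mid
  for (nm in names(pair)) {
    out[[paste("Right", nm)]] <- pair[[nm]] * c(-1, 1, 1)
    out[[paste("Left", nm)]] <- pair[[nm]]
  }
  out
}

#' Names of the 11 initialization landmarks
#'
#' The subset of the 20 validation landmarks used to initialize the
#' rigid registration (midline points plus the orbital, zygomatic and
#' gonial pairs).
#' @export
init_landmark_names <- function() {
  c("Nasion", "Subspinale", "Pogonion",
    "Right Orbitale", "Left Orbitale",
    "Right Frontomalare Orbital", "Left Frontomalare Orbital",
    "Right Zygion", "Left Zygion",
    "Right Gonion", "Left Gonion")
}

landmark_vertex_ids <- function(base) {
  dirs <- validation_landmark_dirs()
  radii <- c(60, 85, 70)
  ids <- vapply(dirs, function(d) {
    d <- d / sqrt(sum(d^2))
    cpp_nearest_vertex(matrix(d * radii, 1), base$vertices)$index
  }, integer(1))
  if (anyDuplicated(ids)) stopf("landmark directions collide on this resolution")
  ids
}

# smooth RBF displacement field evaluated at base vertices, normalized
# to unit RMS; returns n x 3 matrix
rbf_field <- function(v, n_bumps, kernel_sd) {
  ctr <- v[sample.int(nrow(v), n_bumps, replace = TRUE), , drop = FALSE]
  amp <- matrix(rnorm(n_bumps * 3), n_bumps, 3)
  f <- matrix(0, nrow(v), 3)
  for (i in seq_len(n_bumps)) {
    w <- exp(-rowSums(sweep(v, 2, ctr[i, ])^2) / (2 * kernel_sd^2))
    f <- f + outer(w, amp[i, ])
  }
  rms <- sqrt(mean(rowSums(f^2)))
  if (rms > 0) f / rms else f
}

# Remove the similarity-mode component of a normal displacement
# magnitude field: the part of g that is indistinguishable (to first
# order, in the normal projection) from a rotation/translation/scale
# of the whole surface. Individuals generated this way are in
# Procrustes-optimal pose with respect to the base by construction,
# which is the standard morphometric convention and what makes "true
# pose" well-defined at all.
project_out_similarity <- function(g, v, nrm) {
  A <- cbind(v[, 2] * nrm[, 3] - v[, 3] * nrm[, 2],
             v[, 3] * nrm[, 1] - v[, 1] * nrm[, 3],
             v[, 1] * nrm[, 2] - v[, 2] * nrm[, 1],
             nrm, rowSums(v * nrm))
  g - as.numeric(A %*% qr.solve(A, g))
}

# smooth scalar RBF field, unit RMS
rbf_scalar_field <- function(v, n_bumps, kernel_sd) {
  ctr <- v[sample.int(nrow(v), n_bumps, replace = TRUE), , drop = FALSE]
  amp <- rnorm(n_bumps)
  g <- numeric(nrow(v))
  for (i in seq_len(n_bumps)) {
    w <- exp(-rowSums(sweep(v, 2, ctr[i, ])^2) / (2 * kernel_sd^2))
    g <- g + amp[i] * w
  }
  rms <- sqrt(mean(g^2))
  if (rms > 0) g / rms else g
}

random_rotation <- function(sd_deg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- rnorm(1, sd = sd_deg * pi / 180)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Generate a synthetic skull population with ground truth
#'
#' @param spec a [population_spec()].
#' @return an object of class `synthetic_population`: list with
#'   `base` (template-topology base mesh), `landmark_ids`, and
#'   `individuals`, each of which holds `mesh` (the target surface, in
#'   its own pose, possibly truncated/punctured/noisy), `truth_quasi`
#'   (ground-truth [masked_shape()] in target pose), `truth_landmarks`
#'   (ground-truth [landmark_config()]), and `pose` (the rigid pose
#'   applied).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    base <- base_skull_mesh(spec$subdivisions)
    lm_ids <- landmark_vertex_ids(base)
    mirror <- diag(c(-1, 1, 1))
    kernel_sd <- spec$deformation_smoothness / 4
    individuals <- vector("list", spec$n_individuals)
    nrm <- vertex_normals(base)
    mirror_idx <- cpp_nearest_vertex(base$vertices %*% diag(c(-1, 1, 1)),
                                     base$vertices)$index
    for (i in seq_len(spec$n_individuals)) {
      v <- base$vertices
      # individual variation as smooth apposition/resorption along the
      # surface normal (tangential reparameterization carries no shape
      # information and is not generated)
      g <- rbf_scalar_field(v, spec$n_bumps, kernel_sd)
      gm <- g[mirror_idx]
      g_sym <- project_out_similarity((g + gm) / 2, v, nrm)
      g_asym <- project_out_similarity((g - gm) / 2, v, nrm)
      sym_rms <- sqrt(mean(g_sym^2))
      asym_rms <- sqrt(mean(g_asym^2))
      defo <- nrm * (g_sym * spec$deformation_amplitude / max(sym_rms, 1e-12) +
                     g_asym * spec$asymmetry_sd / max(asym_rms, 1e-12))
      size <- 1 + rnorm(1, sd = spec$size_sd)
      vi <- size * (v + defo)
      R <- random_rotation(spec$pose_rotation_sd)
      t_ <- rnorm(3, sd = spec$pose_translation_sd)
      pose <- similarity_transform(R, t_, 1)
      vi <- apply_transform(pose, vi)
      truth_lm <- landmark_config(vi[lm_ids, , drop = FALSE], names(lm_ids),
                                  frame = sprintf("skull%02d", i))
      faces <- base$faces
      # posterior truncation: drop the most -z faces (in subject frame)
      if (spec$truncation_fraction > 0) {
        zc <- (v[faces[, 1], 3] + v[faces[, 2], 3] + v[faces[, 3], 3]) / 3
        cut <- stats::quantile(zc, spec$truncation_fraction)
        faces <- faces[zc > cut, , drop = FALSE]
      }
      for (h in spec$hole_spec %||% list()) {
        hc <- h$dir / sqrt(sum(h$dir^2)) * c(60, 85, 70)
        fc <- (v[faces[, 1], ] + v[faces[, 2], ] + v[faces[, 3], ]) / 3
        faces <- faces[sqrt(rowSums(sweep(fc, 2, hc)^2)) > h$radius, , drop = FALSE]
      }
      kept <- sort(unique(as.vector(faces)))
      lost <- setdiff(lm_ids, kept)
      if (length(lost))
        stopf("truncation/hole removed landmark(s): %s",
              paste(names(lm_ids)[match(lost, lm_ids)], collapse = ", "))
      vm <- vi
      if (spec$vertex_noise > 0)
        vm <- vm + matrix(rnorm(length(vm), sd = spec$vertex_noise),
                          ncol = 3)
      mesh_i <- triangle_mesh(vm, faces)
      individuals[[i]] <- list(
        mesh = mesh_i,
        truth_quasi = masked_shape(vi, base$faces, template_id = "base_skull"),
        truth_landmarks = truth_lm,
        pose = pose, size = size)
    }
    structure(list(base = base, landmark_ids = lm_ids,
                   individuals = individuals, spec = spec),
              class = "synthetic_population")
  })
}

# evaluate the mirrored field: for exactly x-symmetric base meshes the
# mirror image of vertex i is another vertex; find it by nearest match
rbf_eval_mirror <- function(v, f) {
  vm <- v %*% diag(c(-1, 1, 1))
  idx <- cpp_nearest_vertex(vm, v)$index
  fm <- f[idx, , drop = FALSE] %*% diag(c(-1, 1, 1))
  fm
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("synthetic_population: %d individuals, base mesh %d vertices\n",
              length(x$individuals), nrow(x$base$vertices)))
  invisible(x)
}

#' Observer specification for simulated manual landmarking
#'
#' Each observer has a round-to-round noise sd and a smooth systematic
#' bias field. The bias is constant across rounds for an observer, so
#' it inflates inter-observer dispersion but not intra-observer
#' dispersion — the pattern real observer studies show. Defaults model
#' a trained, an intermediate and an untrained observer.
#'
#' @param noise_sd per-observer isotropic placement noise sd (mm).
#' @param bias_amplitude per-observer RMS of the systematic bias field (mm).
#' @param n_rounds landmarking rounds per observer.
#' @param bias_wavelength spatial wavelength of the bias field (mm).
#' @param seed integer seed.
#' @export
observer_spec <- function(noise_sd = c(0.3, 0.6, 0.9),
                          bias_amplitude = c(0.7, 1.0, 1.4),
                          n_rounds = 3, bias_wavelength = 80, seed = 1) {
  stopifnot(all(noise_sd >= 0), length(bias_amplitude) == length(noise_sd))
  structure(list(n_observers = length(noise_sd), noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, n_rounds = n_rounds,
                 bias_wavelength = bias_wavelength, seed = seed),
            class = "observer_spec")
}

#' Simulate repeated manual landmarking by several observers
#'
#' Placement = ground truth + observer bias field (evaluated at the
#' landmark) + iid round noise, re-projected onto the skull surface.
#'
#' @param population a `synthetic_population` from [generate_population()].
#' @param spec an [observer_spec()].
#' @return an [observer_study()] array.
#' @export
simulate_observers <- function(population, spec) {
  stopifnot(inherits(population, "synthetic_population"),
            inherits(spec, "observer_spec"))
  inds <- population$individuals
  K <- length(population$landmark_ids)
  lm_names <- names(population$landmark_ids)
  n_s <- length(inds); n_o <- spec$n_observers; n_r <- spec$n_rounds
  arr <- array(NA_real_, dim = c(n_s, n_o, n_r, K, 3),
               dimnames = list(sprintf("skull%02d", seq_len(n_s)),
                               sprintf("O%d", seq_len(n_o)),
                               sprintf("round%d", seq_len(n_r)),
                               lm_names, c("x", "y", "z")))
  with_seed(spec$seed, {
    kernel_sd <- spec$bias_wavelength / 4
    for (o in seq_len(n_o)) {
      # per-observer smooth bias in the base frame, carried through pose
      base_v <- population$base$vertices
      bias_f <- rbf_field(base_v, 20, kernel_sd) * spec$bias_amplitude[o]
      bias_lm_base <- bias_f[population$landmark_ids, , drop = FALSE]
      for (s in seq_len(n_s)) {
        truth <- inds[[s]]$truth_landmarks$points
        bias <- bias_lm_base %*% t(inds[[s]]$pose$rotation)
        for (r in seq_len(n_r)) {
          pts <- truth + bias + matrix(rnorm(K * 3, sd = spec$noise_sd[o]), K, 3)
          pts <- cpp_closest_points(pts, inds[[s]]$mesh$vertices,
                                    inds[[s]]$mesh$faces)$point
          arr[s, o, r, , ] <- pts
        }
      }
    }
  })
  observer_study(arr)
}

#' Observer study arrays
#'
#' A 5-dimensional array of landmark coordinates indexed
#' skull x observer x round x landmark x axis — the input to all
#' reliability statistics.
#'
#' @param landmarks a 5-d array with dimnames.
#' @export
observer_study <- function(landmarks) {
  stopifnot(length(dim(landmarks)) == 5L, dim(landmarks)[5] == 3L)
  if (any(!is.finite(landmarks))) stopf("observer study contains missing cells")
  structure(list(landmarks = landmarks,
                 skulls = dimnames(landmarks)[[1]],
                 observers = dimnames(landmarks)[[2]],
                 rounds = dimnames(landmarks)[[3]],
                 names = dimnames(landmarks)[[4]]),
            class = "observer_study")
}

#' @export
print.observer_study <- function(x, ...) {
  d <- dim(x$landmarks)
  cat(sprintf("observer_study: %d skulls x %d observers x %d rounds x %d landmarks\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Extract one landmark configuration from an observer study
#' @param study an [observer_study()].
#' @param skull,observer,round indices or names.
#' @export
study_config <- function(study, skull, observer, round) {
  pts <- study$landmarks[skull, observer, round, , ]
  landmark_config(pts, study$names,
                  frame = paste(skull, observer, round, sep = "/"))
}

#' Observer-mean landmark configuration (average over rounds)
#' @param study an [observer_study()].
#' @param skull,observer indices or names.
#' @export
observer_mean_config <- function(study, skull, observer) {
  pts <- apply(study$landmarks[skull, observer, , , , drop = FALSE],
               c(4, 5), mean)
  landmark_config(pts, study$names, frame = paste(skull, observer, "mean", sep = "/"))
}
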