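#' Generalized Procrustes analysis of masked shapes
#'
#' Iterative superimposition: each configuration is centred, optionally
#' scaled to unit centroid size, and rotated onto the running consensus
#' by orthogonal Procrustes; the consensus is recomputed until it
#' changes by less than `tol`. With scaling, the returned consensus is
#' rescaled to the mean of the original centroid sizes so it keeps
#' millimetre units.
#'
#' @param shapes list of [masked_shape()] objects or Q x 3 matrices
#'   with identical Q.
#' @param with_scaling remove size by scaling to unit centroid size.
#' @param tol convergence tolerance on the consensus change.
#' @param max_iter iteration cap.
#' @return an object of class `gpa`: list with `mean` (consensus Q x 3,
#'   mm), `aligned` (list of aligned Q x 3 matrices, consensus scale),
#'   `centroid_sizes` (original sizes, mm), `iterations`.
#' @export
gpa <- function(shapes, with_scaling = TRUE, tol = 1e-10, max_iter = 100) {
  mats <- lapply(shapes, function(s) if (inherits(s, "masked_shape")) s$quasi
                 else as_point_matrix(s, "shape"))
  if (length(mats) < 2L) stopf("GPA needs at least 2 shapes")
  q <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == q))
    stopf("all shapes must share the same number of quasi-landmarks (Q = %d)", q)
  cs <- vapply(mats, centroid_size, 0)
  centred <- lapply(mats, function(m) sweep(m, 2, colMeans(m)))
  if (with_scaling) centred <- Map(function(m, s) m / s, centred, cs)
  # deterministic, order-independent choice of the starting reference:
  # GPA fixes global orientation only up to the initial frame, so the
  # reference is picked by a content hash rather than list position
  key <- vapply(centred, function(m) sum(m * seq_along(m)), 0)
  ref <- centred[[which.min(key)]]
  it <- 0L
  repeat {
    it <- it + 1L
    aligned <- lapply(centred, rotate_onto, ref = ref)
    newmean <- Reduce(`+`, aligned) / length(aligned)
    if (with_scaling) newmean <- newmean / centroid_size(newmean)
    delta <- sqrt(sum((newmean - ref)^2))
    ref <- newmean
    if (delta < tol || it >= max_iter) break
  }
  aligned <- lapply(centred, rotate_onto, ref = ref)
  scale_back <- if (with_scaling) mean(cs) else 1
  structure(list(mean = ref * scale_back,
                 aligned = lapply(aligned, `*`, scale_back),
                 centroid_sizes = cs, iterations = it,
                 with_scaling = with_scaling),
            class = "gpa")
}

rotate_onto <- function(m, ref) {
  s <- svd(crossprod(ref, m))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  m %*% R
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("gpa: %d shapes x %d quasi-landmarks, %s, converged in %d iterations\n",
              length(x$aligned), nrow(x$mean),
              if (x$with_scaling) "with scaling" else "without scaling",
              x$iterations))
  cat(sprintf("  centroid sizes (mm): %.2f .. %.2f (mean %.2f)\n",
              min(x$centroid_sizes), max(x$centroid_sizes),
              mean(x$centroid_sizes)))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root-mean-square distance after removing translation, rotation and
#' (optionally) scale.
#' @param a,b K x 3 matrices or [masked_shape()] objects.
#' @param with_scaling remove scale.
#' @export
procrustes_distance <- function(a, b, with_scaling = TRUE) {
  ma <- if (inherits(a, "masked_shape")) a$quasi else as_point_matrix(a)
  mb <- if (inherits(b, "masked_shape")) b$quasi else as_point_matrix(b)
  ma <- sweep(ma, 2, colMeans(ma)); mb <- sweep(mb, 2, colMeans(mb))
  if (with_scaling) { ma <- ma / centroid_size(ma); mb <- mb / centroid_size(mb) }
  sqrt(mean(rowSums((rotate_onto(mb, ma) - ma)^2)))
}

#' Make a mesh exactly mirror-symmetric about x = 0
#'
#' Vertices with `|x| < tol` are snapped to the plane, the `x >= 0`
#' half is kept, and it is mirrored to the other side. The output's
#' vertex set maps to itself under x-negation.
#'
#' @param mesh a roughly bilaterally symmetric [triangle_mesh()].
#' @param tol midline snap tolerance in mm (default 0.5).
#' @return a [triangle_mesh()].
#' @export
plane_symmetrize <- function(mesh, tol = 0.5) {
  v <- mesh$vertices
  v[abs(v[, 1]) < tol, 1] <- 0
  if (!any(v[, 1] == 0))
    warning("no vertices within the midline snap tolerance; seam will be open")
  keep_v <- which(v[, 1] >= 0)
  remap <- integer(nrow(v)); remap[keep_v] <- seq_along(keep_v)
  f <- mesh$faces
  fkeep <- f[apply(matrix(v[f, 1] >= 0, ncol = 3), 1, all), , drop = FALSE]
  fkeep[] <- remap[fkeep]
  vk <- v[keep_v, , drop = FALSE]
  pos <- which(vk[, 1] > 0)
  mirror_map <- integer(nrow(vk))
  mirror_map[vk[, 1] == 0] <- which(vk[, 1] == 0)
  mv <- vk[pos, , drop = FALSE]; mv[, 1] <- -mv[, 1]
  mirror_map[pos] <- nrow(vk) + seq_along(pos)
  f2 <- matrix(mirror_map[fkeep], ncol = 3)[, c(1, 3, 2), drop = FALSE]
  triangle_mesh(rbind(vk, mv), rbind(fkeep, f2))
}

#' Discover the mirror pairing of a symmetric shape
#'
#' Matches every vertex to its nearest neighbour under x-negation and
#' requires the match to be mutual. On an exactly symmetric shape this
#' is a perfect involution; midline vertices pair with themselves.
#'
#' @param x a [triangle_mesh()], [masked_shape()] or n x 3 matrix.
#' @param max_dist pairs farther than this (mm) after mirroring raise
#'   an error.
#' @return integer vector `p` with `p[p[i]] == i` for all `i`.
#' @export
mirror_pairing <- function(x, max_dist = 1e-6) {
  v <- if (inherits(x, "triangle_mesh")) x$vertices
  else if (inherits(x, "masked_shape")) x$quasi else as_point_matrix(x)
  vm <- v %*% diag(c(-1, 1, 1))
  nn <- cpp_nearest_vertex(vm, v)
  p <- nn$index
  if (any(nn$distance > max_dist))
    stopf("shape is not mirror-symmetric: %d vertices unmatched beyond %g mm",
          sum(nn$distance > max_dist), max_dist)
  if (!all(p[p] == seq_along(p)))
    stopf("mirror matching is not an involution; shape is not symmetric enough")
  p
}

#' Symmetrize a shape by averaging it with its reflection
#'
#' The shape is reflected (x negated), re-indexed by the mirror
#' pairing, aligned back onto the original by orthogonal Procrustes
#' (rotation + translation), and averaged with the original. The
#' output is exactly symmetric under the pairing.
#'
#' @param shape a [masked_shape()] or Q x 3 matrix.
#' @param pairing involution from [mirror_pairing()] (computed on the
#'   template).
#' @return same type as the input.
#' @export
reflection_average <- function(shape, pairing) {
  m <- if (inherits(shape, "masked_shape")) shape$quasi else as_point_matrix(shape)
  pairing <- as.integer(pairing)
  if (!all(pairing[pairing] == seq_along(pairing)))
    stopf("pairing is not an involution")
  refl <- (m %*% diag(c(-1, 1, 1)))[pairing, , drop = FALSE]
  # rigidly align the reflection onto the original before averaging
  cm <- colMeans(m); cr <- colMeans(refl)
  ra <- rotate_onto(sweep(refl, 2, cr), sweep(m, 2, cm))
  avg <- (sweep(m, 2, cm) + ra) / 2
  avg <- sweep(avg, 2, cm, "+")
  # enforce exact symmetry under (reflect + pairing)
  ravg <- (avg %*% diag(c(-1, 1, 1)))[pairing, , drop = FALSE]
  out <- (avg + ravg) / 2
  if (inherits(shape, "masked_shape")) { shape$quasi <- out; shape } else out
}

#' Asymmetry score of a shape under a mirror pairing
#'
#' RMS distance between the shape and its reflection re-indexed by the
#' pairing (after Procrustes alignment of the reflection).
#' @inheritParams reflection_average
#' @export
asymmetry_score <- function(shape, pairing) {
  m <- if (inherits(shape, "masked_shape")) shape$quasi else as_point_matrix(shape)
  refl <- (m %*% diag(c(-1, 1, 1)))[pairing, , drop = FALSE]
  cm <- colMeans(m); cr <- colMeans(refl)
  ra <- sweep(rotate_onto(sweep(refl, 2, cr), sweep(m, 2, cm)), 2, cm, "+")
  sqrt(mean(rowSums((m - ra)^2)))
}

#' Build the average symmetric template mask
#'
#' Registers a preliminary mask to every target, averages the resulting
#' masked shapes by generalized Procrustes analysis (with scaling),
#' rescales the consensus to the mean centroid size, and symmetrizes it
#' by reflection averaging. The output carries the preliminary mask's
#' topology.
#'
#' @param targets list of target [triangle_mesh()] objects.
#' @param preliminary_mask the preliminary mask [triangle_mesh()]
#'   (assumed roughly bilaterally symmetric about x = 0).
#' @param mask_landmarks initialization landmarks on the preliminary
#'   mask.
#' @param target_landmarks list of matching [landmark_config()]s, one
#'   per target.
#' @param cfg [nonrigid_config()] passed to registration.
#' @param pairing optional mirror pairing of the mask vertices;
#'   computed by [mirror_pairing()] on the symmetrized mask if absent.
#' @return a [triangle_mesh()] template with attribute `pairing`.
#' @export
build_template <- function(targets, preliminary_mask, mask_landmarks,
                           target_landmarks, cfg = nonrigid_config(),
                           pairing = NULL) {
  if (length(targets) < 2L) stopf("need at least 2 targets")
  if (length(target_landmarks) != length(targets))
    stopf("one landmark configuration per target required")
  masked <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    reg <- tryCatch(
      register_mask(preliminary_mask, targets[[i]], mask_landmarks,
                    target_landmarks[[i]], cfg = cfg),
      error = function(e) stopf("registration failed for target %d: %s",
                                i, conditionMessage(e)))
    masked[[i]] <- reg$masked
  }
  g <- gpa(masked, with_scaling = TRUE)
  consensus <- g$mean
  if (is.null(pairing)) {
    # the pairing lives on the template topology, so it is derived
    # from the (roughly symmetric) preliminary mask, with a tolerance
    # of half its typical edge length
    pairing <- mirror_pairing(preliminary_mask,
                              max_dist = mean(edge_lengths(preliminary_mask)) / 2)
  }
  templ <- reflection_average(consensus, pairing)
  out <- triangle_mesh(templ, preliminary_mask$faces, clean = FALSE)
  attr(out, "pairing") <- pairing
  out
}
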