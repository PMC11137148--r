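#' Refine a landmark similarity fit against normal displacement
#'
#' Craniofacial surfaces differ between individuals predominantly by
#' displacement along the surface normal (bone apposition/resorption),
#' so a target landmark is best treated as lying anywhere on the line
#' through its true position along the local normal. This routine
#' iteratively re-solves the similarity fit with each target landmark
#' replaced by its projection onto that line, which removes the pose
#' bias that normal-direction shape differences induce in a plain
#' least-squares landmark fit.
#'
#' @param source landmarks on the template ([landmark_config()]).
#' @param target corresponding landmarks on the target.
#' @param source_normals K x 3 unit normals of the template surface at
#'   the source landmarks (rotated along with the current estimate).
#' @param init optional initial [similarity_transform()]; default is
#'   the plain similarity fit.
#' @param iterations refinement iterations.
#' @param with_scale solve for uniform scale.
#' @return a [similarity_transform()] with attribute `rms` (tangential
#'   residual RMS, mm).
#' @export
similarity_from_landmarks_normal <- function(source, target, source_normals,
                                             init = NULL, iterations = 25,
                                             with_scale = TRUE) {
  stopifnot(inherits(source, "landmark_config"), inherits(target, "landmark_config"))
  source_normals <- normalize_rows(as_point_matrix(source_normals, "normals"))
  tr <- init %||% similarity_from_landmarks(source, target, with_scale = with_scale)
  y <- target$points[source$names, , drop = FALSE]
  for (k in seq_len(iterations)) {
    fitted <- apply_transform(tr, source$points)
    n_t <- source_normals %*% t(tr$rotation)
    yadj <- y + n_t * rowSums((fitted - y) * n_t)
    tr <- similarity_from_landmarks(source,
                                    landmark_config(yadj, source$names, target$frame),
                                    with_scale = with_scale)
  }
  fitted <- apply_transform(tr, source$points)
  n_t <- source_normals %*% t(tr$rotation)
  res <- fitted - y
  res_t <- res - n_t * rowSums(res * n_t)
  attr(tr, "rms") <- sqrt(mean(rowSums(res_t^2)))
  tr
}

#' Register the template mask to a target skull
#'
#' The full template-to-target alignment: (1) similarity initialization
#' from sparse named landmarks placed on both the mask and the target,
#' refined against normal-direction shape differences
#' ([similarity_from_landmarks_normal()]); (2) optional rigid
#' iterative-closest-point refinement ([rigid_icp()], useful when the
#' initialization landmarks are few or unreliable); (3) non-rigid
#' adaptation of the mask shape to the target
#' ([nonrigid_register()]). The result expresses the target as the
#' mask's quasi-landmarks in anatomical correspondence.
#'
#' @param mask template [triangle_mesh()].
#' @param target target [triangle_mesh()].
#' @param mask_landmarks initialization landmarks on the mask
#'   ([landmark_config()]).
#' @param target_landmarks the same named landmarks on the target.
#' @param cfg a [nonrigid_config()].
#' @param refine rigid refinement after the landmark fit:
#'   `"normal_icp"` (default) uses [normal_shooting_icp()], whose
#'   converged pose does not depend on the initialization landmarks —
#'   repeated registrations of the same skull then agree almost
#'   exactly; `"icp"` uses classic closest-point [rigid_icp()] (more
#'   robust on severely truncated targets, but its unconstrained
#'   surface fit trades correspondence fidelity for surface fit);
#'   `"none"` keeps the landmark fit.
#' @param icp_max_iter iteration cap for the refinement.
#' @return an object of class `mask_registration`: list with `masked`
#'   (the [masked_shape()] in target frame), `transform` (the rigid
#'   initialization actually used), `final_distance` (mean mask-to-
#'   target closest distance, mm), `init_rms`, and `cfg`.
#' @export
register_mask <- function(mask, target, mask_landmarks, target_landmarks,
                          cfg = nonrigid_config(),
                          refine = c("normal_icp", "icp", "none"),
                          icp_max_iter = 100) {
  stopifnot(inherits(mask, "triangle_mesh"), inherits(target, "triangle_mesh"))
  refine <- match.arg(refine)
  nrm <- vertex_normals(mask)
  attr(mask, "cached_normals") <- nrm
  lm_vid <- cpp_nearest_vertex(mask_landmarks$points, mask$vertices)$index
  tr <- similarity_from_landmarks_normal(mask_landmarks, target_landmarks,
                                         nrm[lm_vid, , drop = FALSE])
  tr <- switch(refine,
               normal_icp = normal_shooting_icp(mask, target, tr,
                                                max_iter = icp_max_iter),
               icp = rigid_icp(mask, target, tr, max_iter = icp_max_iter),
               none = tr)
  aligned <- apply_transform(tr, mask)
  attr(aligned, "cached_normals") <- nrm %*% t(tr$rotation)
  masked <- nonrigid_register(aligned, target, cfg)
  structure(list(masked = masked, transform = tr,
                 final_distance = attr(masked, "final_distance"),
                 init_rms = attr(tr, "rms"), cfg = cfg),
            class = "mask_registration")
}

#' @export
print.mask_registration <- function(x, ...) {
  cat("mask_registration\n")
  cat(sprintf("  quasi-landmarks : %d\n", nrow(x$masked$quasi)))
  cat(sprintf("  init landmark residual RMS : %.3f mm\n", x$init_rms))
  cat(sprintf("  final mask-to-target distance : %.3f mm\n", x$final_distance))
  invisible(x)
}

#' @export
summary.mask_registration <- function(object, ...) {
  print(object)
  print(object$transform)
  invisible(object)
}
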