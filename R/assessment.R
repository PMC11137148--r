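#' Normal-ray distance from a masked shape to the original skull
#'
#' For every quasi-landmark, the distance to the first ray-surface
#' intersection cast along its normal in either direction (the nearer
#' of the two). Rays that hit nothing within `max_range` are censored
#' at `max_range` and flagged. This measures how far the wrapped mask
#' sits from actual bone: large values indicate the mask is bridging a
#' hole or a region absent from the scan.
#'
#' @param masked a [masked_shape()].
#' @param original the original skull [triangle_mesh()] (before
#'   wrapping).
#' @param normals optional Q x 3 unit normals on the masked
#'   (template-topology) surface; computed from it if missing.
#' @param max_range censoring range in mm (default 50).
#' @return list with `distance` (Q-vector, mm) and `censored`
#'   (logical Q-vector).
#' @export
normal_distance <- function(masked, original, normals = NULL, max_range = 50) {
  stopifnot(inherits(masked, "masked_shape"), inherits(original, "triangle_mesh"))
  if (is.null(normals)) normals <- vertex_normals(as_mesh(masked))
  normals <- as_point_matrix(normals, "normals")
  len <- vnorm(normals)
  if (any(abs(len - 1) > 1e-6 & len > 0))
    stopf("normals must be unit length")
  ray <- cpp_ray_distance(masked$quasi, normals, original$vertices,
                          original$faces, max_range)
  list(distance = ray$distance, censored = !ray$hit)
}

#' Flag true vs gap quasi-landmarks
#'
#' A quasi-landmark is a "gap" landmark if its normal-ray distance
#' exceeds `threshold` in more than half of the skulls; otherwise it
#' is "true" (lies on actual bone). The flags are then symmetrized
#' conservatively: a mirror pair is kept as true only if both members
#' are true.
#'
#' @param distances n_skulls x Q matrix of [normal_distance()] values.
#' @param threshold gap distance threshold in mm (default 10).
#' @param pairing mirror pairing involution from [mirror_pairing()];
#'   `NULL` skips symmetrization.
#' @return object of class `true_landmark_mask`: list with `flags`
#'   (logical Q-vector, `TRUE` = true/solid landmark), `exceed_counts`,
#'   `n_skulls`, `threshold`.
#' @export
flag_true_landmarks <- function(distances, threshold = 10, pairing = NULL) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 1L) stopf("need at least one skull")
  counts <- colSums(d > threshold)
  flags <- counts <= n / 2  # gap iff exceeding in MORE than half
  if (!is.null(pairing)) {
    pairing <- as.integer(pairing)
    if (length(pairing) != ncol(d) || !all(pairing[pairing] == seq_along(pairing)))
      stopf("pairing must be an involution over the %d quasi-landmarks", ncol(d))
    flags <- flags & flags[pairing]
  }
  structure(list(flags = flags, exceed_counts = as.integer(counts),
                 n_skulls = n, threshold = threshold),
            class = "true_landmark_mask")
}

#' @export
print.true_landmark_mask <- function(x, ...) {
  cat(sprintf("true_landmark_mask: %d of %d quasi-landmarks true (threshold %g mm, %d skulls)\n",
              sum(x$flags), length(x$flags), x$threshold, x$n_skulls))
  invisible(x)
}

#' Write gap-landmark vertex IDs to a text file
#'
#' One 0-based vertex ID per line, the conventional published format
#' for marking quasi-landmarks that do not define true points on bone.
#'
#' @param mask a `true_landmark_mask`.
#' @param path output path.
#' @export
write_gap_ids <- function(mask, path) {
  writeLines(as.character(which(!mask$flags) - 1L), path)
  invisible(path)
}

#' Topology fidelity of the masking process
#'
#' Mean and sd of the normal-ray distance between the masked skull and
#' the original, restricted to true landmarks — how much the
#' wrap/remesh/registration chain altered the represented surface.
#'
#' @param masked a [masked_shape()].
#' @param original original skull [triangle_mesh()].
#' @param true_flags logical Q-vector (e.g. from
#'   [flag_true_landmarks()]); default keeps all quasi-landmarks.
#' @param max_range ray censoring range (mm).
#' @return list with `mean`, `sd` (mm) and `distance` (full Q-vector
#'   with `NA` outside the true set).
#' @export
topology_fidelity <- function(masked, original, true_flags = NULL,
                              max_range = 50) {
  nd <- normal_distance(masked, original, max_range = max_range)
  flags <- true_flags %||% rep(TRUE, length(nd$distance))
  if (!any(flags)) stopf("no true landmarks to summarize")
  d <- nd$distance
  d[!flags] <- NA_real_
  list(mean = mean(d[flags]), sd = stats::sd(d[flags]), distance = d)
}
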