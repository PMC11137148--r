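#' Barycentric anchors: landmarks as weights over quasi-landmarks
#'
#' A sparse landmark is encoded as barycentric weights over its three
#' closest quasi-landmarks. Because quasi-landmark IDs correspond
#' across individuals, the anchor transfers the landmark's relative
#' position from one masked skull to another.
#'
#' @param quasi_ids 3 distinct quasi-landmark indices (1-based).
#' @param weights 3 weights summing to 1 (tolerance 1e-9); negative
#'   weights (extrapolation) are allowed.
#' @export
barycentric_anchor <- function(quasi_ids, weights) {
  quasi_ids <- as.integer(quasi_ids)
  weights <- as.numeric(weights)
  if (length(quasi_ids) != 3L || length(weights) != 3L)
    stopf("anchor needs exactly 3 ids and 3 weights")
  if (anyDuplicated(quasi_ids)) stopf("quasi ids must be distinct")
  if (abs(sum(weights) - 1) > 1e-9)
    stopf("weights must sum to 1 (got %.12f)", sum(weights))
  structure(list(quasi_ids = quasi_ids, weights = weights),
            class = "barycentric_anchor")
}

#' Encode a landmark as a barycentric anchor
#'
#' Finds the 3 quasi-landmarks closest to the point (ties broken by
#' lowest index) and computes the barycentric coordinates of the
#' point's orthogonal projection onto their plane. Near-collinear
#' triples (condition number above 1e8) fall back to normalized
#' inverse-distance weights.
#'
#' @param landmark 3D point (mm).
#' @param masked a [masked_shape()] (or Q x 3 matrix) with Q >= 3.
#' @return a [barycentric_anchor()].
#' @export
encode_barycentric <- function(landmark, masked) {
  p <- as.numeric(landmark)
  if (length(p) != 3L || any(!is.finite(p))) stopf("landmark must be a finite 3D point")
  q <- if (inherits(masked, "masked_shape")) masked$quasi else as_point_matrix(masked)
  if (nrow(q) < 3L) stopf("need at least 3 quasi-landmarks")
  d <- sqrt(colSums((t(q) - p)^2))
  ids <- order(d, seq_along(d))[1:3]  # stable: ties to lowest index
  a <- q[ids[1], ]; b <- q[ids[2], ]; c_ <- q[ids[3], ]
  e1 <- b - a; e2 <- c_ - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  cond <- tryCatch(kappa(G, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e8) {
    w <- 1 / pmax(d[ids], 1e-12)
    w <- w / sum(w)
  } else {
    uv <- solve(G, rhs)
    w <- c(1 - uv[1] - uv[2], uv[1], uv[2])
  }
  barycentric_anchor(ids, w)
}

#' Decode a barycentric anchor on a masked shape
#'
#' @param anchor a [barycentric_anchor()].
#' @param masked a [masked_shape()] (or Q x 3 matrix).
#' @return 3D point: the weighted sum of the anchored quasi-landmarks.
#' @export
decode_barycentric <- function(anchor, masked) {
  q <- if (inherits(masked, "masked_shape")) masked$quasi else as_point_matrix(masked)
  if (any(anchor$quasi_ids < 1L | anchor$quasi_ids > nrow(q)))
    stopf("anchor ids out of range [1, %d]", nrow(q))
  as.numeric(anchor$weights %*% q[anchor$quasi_ids, , drop = FALSE])
}

#' Transfer sparse landmarks to a target skull
#'
#' Each landmark is encoded as a barycentric anchor on every training
#' masked skull; each training anchor is decoded on the target's
#' masked shape; the decoded positions are averaged; and the average
#' is projected to the exact closest point on the target surface
#' (the average of positions decoded from different skulls need not
#' lie on it).
#'
#' @param train list of `list(masked = masked_shape, landmarks =
#'   landmark_config)` training pairs; landmark names must agree.
#' @param target_masked [masked_shape()] of the target skull.
#' @param target_mesh target [triangle_mesh()] for the surface
#'   projection.
#' @return a [landmark_config()] of automatic landmarks on the target
#'   surface.
#' @export
transfer_landmarks <- function(train, target_masked, target_mesh) {
  if (length(train) < 1L) stopf("at least one training shape required")
  names0 <- train[[1]]$landmarks$names
  for (tr in train) {
    d1 <- setdiff(names0, tr$landmarks$names)
    d2 <- setdiff(tr$landmarks$names, names0)
    if (length(d1) || length(d2))
      stopf("training landmark names differ: [%s] vs [%s]",
            paste(d1, collapse = ","), paste(d2, collapse = ","))
  }
  out <- matrix(NA_real_, length(names0), 3)
  for (k in seq_along(names0)) {
    dec <- vapply(train, function(tr) {
      anc <- encode_barycentric(tr$landmarks$points[names0[k], ], tr$masked)
      decode_barycentric(anc, target_masked)
    }, numeric(3))
    out[k, ] <- rowMeans(dec)
  }
  proj <- cpp_closest_points(out, target_mesh$vertices, target_mesh$faces)
  landmark_config(proj$point, names0, frame = "transferred")
}

#' Leave-one-out evaluation of automatic landmark transfer
#'
#' Each skull in turn is held out; its landmarks are predicted by
#' [transfer_landmarks()] from all other skulls and compared with its
#' own manual landmarks, per observer and for the observer average.
#'
#' @param shapes list of `list(masked = masked_shape, mesh =
#'   triangle_mesh, landmarks = named list of landmark_config per
#'   observer)` — use observer-averaged configurations upstream if
#'   desired; an entry named `"mean"` is treated as the observer
#'   average.
#' @return object of class `loo_result`: `errors` is a long data frame
#'   (skull, landmark, observer, distance in mm); `summary` gives
#'   per-landmark Mean/Std/Min/Max of the observer-average distances;
#'   `mean` is the grand mean of observer-average distances.
#' @export
loo_evaluate <- function(shapes) {
  n <- length(shapes)
  if (n < 3L) stopf("leave-one-out needs at least 3 skulls")
  obs_names <- names(shapes[[1]]$landmarks)
  rows <- list()
  transferred <- lapply(seq_len(n), function(i) list())
  for (held in seq_len(n)) {
    target <- shapes[[held]]
    for (obs in obs_names) {
      train <- lapply(shapes[-held], function(s)
        list(masked = s$masked, landmarks = s$landmarks[[obs]]))
      auto <- transfer_landmarks(train, target$masked, target$mesh)
      transferred[[held]][[obs]] <- auto
      manual <- target$landmarks[[obs]]
      d <- vnorm(auto$points[manual$names, , drop = FALSE] - manual$points)
      rows[[length(rows) + 1L]] <- data.frame(
        skull = held, landmark = manual$names, observer = obs, distance = d,
        row.names = NULL)
    }
  }
  errors <- do.call(rbind, rows)
  avg_obs <- if ("mean" %in% obs_names) "mean" else obs_names[1]
  eavg <- errors[errors$observer == avg_obs, ]
  per_lm <- do.call(rbind, lapply(split(eavg$distance, eavg$landmark), function(x)
    data.frame(Mean = mean(x), Std = stats::sd(x), Min = min(x), Max = max(x))))
  per_lm <- data.frame(Landmark = rownames(per_lm), per_lm, row.names = NULL)
  structure(list(errors = errors, summary = per_lm, mean = mean(eavg$distance),
                 observer_used = avg_obs, transferred = transferred),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("leave-one-out transfer: %d skulls, %d landmarks\n",
              length(unique(x$errors$skull)), nrow(x$summary)))
  cat(sprintf("  mean distance (observer '%s'): %.3f mm\n",
              x$observer_used, x$mean))
  invisible(x)
}
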