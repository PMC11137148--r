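#' Similarity transforms
#'
#' A `similarity_transform` holds a rotation (proper orthonormal,
#' det +1), a translation (mm) and a positive uniform scale, applied
#' as `y = scale * R x + t`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (mm).
#' @param scale positive scalar.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-6)) ||
      det(rotation) < 0)
    stopf("rotation must be proper orthonormal (det +1)")
  if (scale <= 0) stopf("scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("similarity_transform: rotation %.2f deg, scale %.4f, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$scale, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.null(attr(x, "rms"))) cat(sprintf("  landmark residual RMS: %.4g mm\n", attr(x, "rms")))
  invisible(x)
}

#' Apply a similarity transform to points or a mesh
#' @param transform a [similarity_transform()].
#' @param x an n x 3 matrix, [triangle_mesh()], [landmark_config()] or
#'   [masked_shape()].
#' @export
apply_transform <- function(transform, x) {
  tp <- function(p) sweep(transform$scale * p %*% t(transform$rotation),
                          2, transform$translation, "+")
  if (inherits(x, "triangle_mesh")) { x$vertices <- tp(x$vertices); x }
  else if (inherits(x, "landmark_config")) {
    landmark_config(tp(x$points), x$names, x$frame)
  } else if (inherits(x, "masked_shape")) { x$quasi <- tp(x$quasi); x }
  else tp(as_point_matrix(x))
}

#' Compose two similarity transforms (`b` after `a`)
#' @param a,b [similarity_transform()] objects.
#' @export
compose_transform <- function(b, a) {
  similarity_transform(b$rotation %*% a$rotation,
                       b$scale * b$rotation %*% a$translation + b$translation,
                       b$scale * a$scale)
}

#' Least-squares similarity transform between named landmark sets
#'
#' Solves `argmin sum_i || s R x_i + t - y_i ||^2` over rotation,
#' translation and uniform scale (Umeyama's closed form via SVD of the
#' cross-covariance). Landmarks are matched by name; at least three
#' non-collinear pairs are required. The residual RMS (mm) is attached
#' as attribute `rms`.
#'
#' @param source,target [landmark_config()] objects with identical names.
#' @param with_scale solve for scale (default) or fix it at 1.
#' @return a [similarity_transform()] mapping source onto target.
#' @export
similarity_from_landmarks <- function(source, target, with_scale = TRUE) {
  stopifnot(inherits(source, "landmark_config"), inherits(target, "landmark_config"))
  missing <- setdiff(source$names, target$names)
  extra <- setdiff(target$names, source$names)
  if (length(missing) || length(extra))
    stopf("landmark names differ: missing in target [%s]; missing in source [%s]",
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  x <- source$points
  y <- target$points[source$names, , drop = FALSE]
  if (nrow(x) < 3L) stopf("at least 3 landmarks required, got %d", nrow(x))
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  if (svd(xc)$d[2] < 1e-9 * max(svd(xc)$d[1], 1))
    stopf("landmarks are collinear; similarity transform is underdetermined")
  S <- crossprod(yc, xc) / nrow(x)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(xc^2) / nrow(x)
  s <- if (with_scale) sum(diag(D) * sv$d) / varx else 1
  t_ <- my - s * as.numeric(R %*% mx)
  tr <- similarity_transform(R, t_, s)
  fitted <- apply_transform(tr, x)
  attr(tr, "rms") <- sqrt(mean(rowSums((fitted - y)^2)))
  tr
}

#' Rigid (similarity) iterative closest point refinement
#'
#' Alternates exact closest-surface-point correspondence with a
#' similarity-transform update, using trimmed correspondences (the
#' worst `trim` fraction by residual is excluded each iteration) to
#' tolerate partial targets such as truncated cone-beam CT fields of
#' view. Stops when the relative improvement of the trimmed RMS falls
#' below `tol` or after `max_iter` iterations; errors out if the
#' objective increases, which indicates a bad initialization.
#'
#' @param mask source [triangle_mesh()] (the template).
#' @param target target [triangle_mesh()].
#' @param init initial [similarity_transform()] (e.g. from
#'   [similarity_from_landmarks()]).
#' @param max_iter maximum ICP iterations.
#' @param trim fraction of worst correspondences dropped (default 0.2).
#' @param with_scale refine uniform scale as well as rotation/translation.
#' @param tol relative-improvement stopping threshold.
#' @return a [similarity_transform()] with attributes `rms` (final
#'   trimmed RMS, mm) and `iterations`.
#' @export
rigid_icp <- function(mask, target, init = similarity_transform(),
                      max_iter = 50, trim = 0.2, with_scale = TRUE,
                      tol = 1e-6) {
  stopifnot(inherits(mask, "triangle_mesh"), inherits(target, "triangle_mesh"))
  v0 <- mask$vertices
  tr <- init
  bb <- apply(target$vertices, 2, range)
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  obj_prev <- Inf
  it_done <- 0L
  for (it in seq_len(max_iter)) {
    v <- apply_transform(tr, v0)
    cp <- cpp_closest_points(v, target$vertices, target$faces)
    if (it == 1L && median(cp$distance) > 0.25 * diag_len)
      stopf("initial alignment too poor for ICP: median closest distance %.1f mm vs target diagonal %.1f mm",
            median(cp$distance), diag_len)
    keep <- cp$distance <= stats::quantile(cp$distance, 1 - trim)
    obj <- sqrt(mean(cp$distance[keep]^2))
    if (obj > obj_prev * (1 + 1e-8) + 1e-9 && it > 2L)
      stopf("ICP objective increased at iteration %d (%.4g -> %.4g); bad initialization?",
            it, obj_prev, obj)
    if (is.finite(obj_prev) && (obj_prev - obj) < tol * max(obj_prev, 1e-12)) {
      it_done <- it; obj_prev <- min(obj, obj_prev); break
    }
    obj_prev <- obj
    it_done <- it
    src <- landmark_config(v0[keep, , drop = FALSE],
                           as.character(seq_len(sum(keep))))
    dst <- landmark_config(cp$point[keep, , drop = FALSE],
                           as.character(seq_len(sum(keep))))
    tr <- similarity_from_landmarks(src, dst, with_scale = with_scale)
    attr(tr, "rms") <- NULL
  }
  attr(tr, "rms") <- obj_prev
  attr(tr, "iterations") <- it_done
  tr
}

#' Normal-shooting similarity refinement
#'
#' Refines a similarity transform by casting rays from the template's
#' vertices along its own (transformed) vertex normals and solving, in
#' closed linearized form, for the rotation/translation/scale update
#' that best absorbs the normal-projected ray distances. Because
#' anatomical surface differences are predominantly displacements
#' along the surface normal, the normal-projected metric separates
#' pose from shape difference far better than free closest-point ICP,
#' which trades pose accuracy for surface fit. The iteration is a
#' surface-driven attractor: perturbing the initialization does not
#' change the converged pose, which is what makes repeated
#' registrations of the same skull agree.
#'
#' @param mask template [triangle_mesh()].
#' @param target target [triangle_mesh()].
#' @param init initial [similarity_transform()] (e.g. a landmark fit).
#' @param max_iter iteration cap.
#' @param max_range ray censoring range in mm; rays longer than this
#'   are ignored (default 20, several times the typical shape
#'   difference — long rays are usually wrong-sheet hits).
#' @param with_scale refine uniform scale too.
#' @param min_hit_fraction error out if fewer rays than this hit.
#' @param tol stop when the update is below this angle/translation.
#' @return a [similarity_transform()] with attribute `rms` (RMS of the
#'   normal-projected residual, mm).
#' @export
normal_shooting_icp <- function(mask, target, init = similarity_transform(),
                                max_iter = 15, max_range = 40,
                                with_scale = TRUE, min_hit_fraction = 0.5,
                                tol = 1e-6) {
  stopifnot(inherits(mask, "triangle_mesh"), inherits(target, "triangle_mesh"))
  n0 <- attr(mask, "cached_normals") %||% vertex_normals(mask)
  fnorm <- face_unit_normals(target)
  tr <- init
  rms <- NA_real_
  th_prev <- Inf
  for (it in seq_len(max_iter)) {
    x <- apply_transform(tr, mask$vertices)
    n <- n0 %*% t(tr$rotation)
    ray <- cpp_ray_distance(x, n, target$vertices, target$faces, max_range)
    ok <- ray$hit & is.finite(ray$t)
    # drop grazing and wrong-sheet hits: the target surface at the true
    # correspondent faces roughly the same way as the ray
    agree <- rep(FALSE, length(ok))
    agree[ok] <- abs(rowSums(n[ok, , drop = FALSE] *
                             fnorm[ray$face[ok], , drop = FALSE])) >= 0.3
    ok <- ok & agree
    if (mean(ok) < min_hit_fraction)
      stopf("normal-shooting refinement: only %.0f%% of rays hit the target within %g mm",
            100 * mean(ok), max_range)
    t_ <- ray$t[ok]; xk <- x[ok, , drop = FALSE]; nk <- n[ok, , drop = FALSE]
    A <- cbind(xk[, 2] * nk[, 3] - xk[, 3] * nk[, 2],
               xk[, 3] * nk[, 1] - xk[, 1] * nk[, 3],
               xk[, 1] * nk[, 2] - xk[, 2] * nk[, 1],
               nk,
               if (with_scale) rowSums(nk * xk) else NULL)
    z <- qr.solve(A, t_)
    w <- z[1:3]
    th <- sqrt(sum(w^2))
    K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
    R <- if (th < 1e-14) diag(3) else
      diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
    s <- if (with_scale) exp(z[7]) else 1
    tr <- compose_transform(similarity_transform(R, z[4:6], s), tr)
    rms <- sqrt(mean((t_ - A %*% z)^2))
    # stop on convergence, or when the update stops shrinking (the
    # discrete hit set can flicker in a tiny limit cycle)
    if (th < tol && sqrt(sum(z[4:6]^2)) < tol) break
    if (th < 2e-4 && sqrt(sum(z[4:6]^2)) < 5e-3) break
    if (it >= 4L && th >= 0.9 * th_prev) break
    th_prev <- th
  }
  attr(tr, "rms") <- rms
  tr
}

#' Non-rigid registration configuration
#'
#' Parameters of the annealed smoothed-displacement ICP used by
#' [nonrigid_register()]. `stiffness_start`/`stiffness_end` are
#' neighbourhood sizes (graph smoothing passes) annealed geometrically
#' across iterations — large early values move the template almost
#' rigidly, small late values allow local adaptation, reproducing the
#' viscoelastic behaviour class of dense-correspondence frameworks.
#'
#' @param num_iterations total iterations (>= 1).
#' @param stiffness_start,stiffness_end smoothing neighbourhood sizes
#'   (start >= end >= 0).
#' @param correspondence_k neighbours used when pooling reverse
#'   (target-to-mask) correspondences.
#' @param inlier_kappa robust sigma multiplier: forward residuals above
#'   `median + kappa * MAD` are down-weighted to zero.
#' @param use_symmetric_correspondences also pull mask vertices toward
#'   target vertices whose nearest mask vertex they are.
#' @param trim fraction of worst forward correspondences dropped when
#'   they are also large relative to the typical residual (tolerates
#'   truncated or punctured targets).
#' @param correspondence `"normal"` (default): fixed rays along the
#'   aligned template's vertex normals, immune to tangential sliding;
#'   `"closest"`: evolving exact closest-point correspondences.
#' @param normal_max_range ray censoring range in mm for normal mode.
#' @param realign_passes total non-rigid passes; between passes the
#'   template is rigidly re-aligned onto the recovered correspondence
#'   and rays are re-cast.
#' @export
nonrigid_config <- function(num_iterations = 30, stiffness_start = 25,
                            stiffness_end = 2, correspondence_k = 3,
                            inlier_kappa = 3,
                            use_symmetric_correspondences = FALSE,
                            trim = 0.2,
                            correspondence = c("normal", "closest"),
                            normal_max_range = 40, realign_passes = 1) {
  if (num_iterations < 1) stopf("num_iterations must be >= 1")
  if (stiffness_end > stiffness_start)
    stopf("stiffness must decrease: start %s < end %s", stiffness_start, stiffness_end)
  structure(list(num_iterations = as.integer(num_iterations),
                 stiffness_start = stiffness_start,
                 stiffness_end = stiffness_end,
                 correspondence_k = as.integer(correspondence_k),
                 inlier_kappa = inlier_kappa,
                 use_symmetric_correspondences = isTRUE(use_symmetric_correspondences),
                 trim = trim,
                 correspondence = match.arg(correspondence),
                 normal_max_range = normal_max_range,
                 realign_passes = as.integer(realign_passes)),
            class = "nonrigid_config")
}

#' Dense shapes in template correspondence
#'
#' A `masked_shape` is a target skull expressed as the template's Q
#' quasi-landmarks: same vertex count and face list as the template,
#' vertices deformed onto the target. Identical vertex IDs across
#' individuals are in anatomical correspondence.
#'
#' @param quasi Q x 3 coordinate matrix (mm).
#' @param template_faces shared face list of the template.
#' @param template_id identifier of the template topology.
#' @export
masked_shape <- function(quasi, template_faces, template_id = "template") {
  quasi <- as_point_matrix(quasi, "quasi-landmarks")
  structure(list(quasi = quasi, template_faces = template_faces,
                 template_id = template_id),
            class = "masked_shape")
}

#' @export
print.masked_shape <- function(x, ...) {
  cat(sprintf("masked_shape: %d quasi-landmarks (template '%s')\n",
              nrow(x$quasi), x$template_id))
  invisible(x)
}

#' Convert a masked shape to a mesh
#' @param masked a [masked_shape()].
#' @export
as_mesh <- function(masked) {
  triangle_mesh(masked$quasi, masked$template_faces, clean = FALSE)
}

#' Non-rigid template-to-target registration
#'
#' Adapts the (rigidly aligned) template mask to the target surface by
#' annealed smoothed-displacement ICP. Per iteration: (a) forward
#' correspondences by exact closest surface point, optionally augmented
#' with symmetric target-to-mask pulls; (b) robust inlier weights
#' (residuals beyond `median + kappa * MAD` and the worst `trim`
#' fraction get zero weight); (c) the weighted displacement field is
#' diffused over the template graph with the current stiffness
#' (number of smoothing passes), annealed geometrically from
#' `stiffness_start` to `stiffness_end`. The output preserves the
#' template topology and vertex count exactly, so its vertices are
#' quasi-landmarks in correspondence. Vertices whose correspondences
#' are all down-weighted (holes, truncation) are carried by the
#' diffusion of their neighbours' displacements.
#'
#' @param mask template [triangle_mesh()], already rigidly aligned to
#'   the target (see [rigid_icp()]).
#' @param target target [triangle_mesh()].
#' @param cfg a [nonrigid_config()].
#' @return a [masked_shape()] with attribute `final_distance` (mean
#'   closest distance to target over inlier vertices, mm).
#' @export
nonrigid_register <- function(mask, target, cfg = nonrigid_config()) {
  stopifnot(inherits(mask, "triangle_mesh"), inherits(target, "triangle_mesh"))
  cur <- mask
  for (pass in seq_len(max(1L, cfg$realign_passes))) {
    res <- nonrigid_pass(cur, target, cfg,
                         mask_normals = if (pass == 1L)
                           attr(mask, "cached_normals") else NULL)
    if (pass == max(1L, cfg$realign_passes)) break
    # re-align the template rigidly onto the recovered correspondence
    # (rotation + translation; scale stays frozen after the rigid
    # stage) and repeat with freshly cast rays: this removes residual
    # pose error that the initial rigid alignment left behind
    nm <- as.character(seq_len(nrow(cur$vertices)))
    tr <- similarity_from_landmarks(landmark_config(cur$vertices, nm),
                                    landmark_config(res$quasi, nm),
                                    with_scale = FALSE)
    cur <- apply_transform(tr, cur)
  }
  out <- masked_shape(res$quasi, mask$faces)
  attr(out, "final_distance") <- res$final_distance
  out
}

nonrigid_pass <- function(mask, target, cfg, mask_normals = NULL) {
  v <- mask$vertices
  n <- nrow(v)
  nb <- mesh_neighbours(mask)
  stiff <- if (cfg$num_iterations == 1L) cfg$stiffness_end else
    exp(seq(log(max(cfg$stiffness_start, 0.5)),
            log(max(cfg$stiffness_end, 0.5)),
            length.out = cfg$num_iterations))
  stiff <- pmax(0L, as.integer(round(stiff)))
  ray_hit <- NULL
  if (cfg$correspondence == "normal") {
    # normal shooting along the rigidly aligned template's normals,
    # cast once from the template's own vertices: the template cannot
    # slide tangentially along the target, and a target surface that
    # is a displacement of the template along these rays is recovered
    # exactly. Misses (holes, truncation) and wrong-sheet hits fall
    # back to evolving closest-point correspondences and the robust
    # weights.
    ray_n <- mask_normals %||% vertex_normals(mask)
    ray <- cpp_ray_distance(mask$vertices, ray_n, target$vertices,
                            target$faces, cfg$normal_max_range)
    ray_hit <- ray$hit & is.finite(ray$t)
    fnorm <- face_unit_normals(target)
    ray_hit[ray_hit] <- abs(rowSums(
      ray_n[ray_hit, , drop = FALSE] *
        fnorm[ray$face[ray_hit], , drop = FALSE])) >= 0.3
    # field-coherence gate: the true displacement field is smooth, so a
    # hit whose signed distance deviates grossly from its neighbours'
    # is a wrong-sheet intersection and is demoted to a miss
    tsig <- ifelse(ray_hit, ray$t, NA_real_)
    tw <- ifelse(ray_hit, 1, 0)
    nb0 <- mesh_neighbours(mask)
    sm <- cpp_diffuse_field(cbind(ifelse(ray_hit, ray$t, 0), 0, 0) * tw,
                            tw, nb0$offs, nb0$nbr, 1L)
    tbar <- ifelse(sm$den > 1e-12, sm$num[, 1] / pmax(sm$den, 1e-12), 0)
    dev <- abs(tsig - tbar)
    cut <- max(5 * stats::median(dev[ray_hit]) + 1, 5)
    ray_hit[ray_hit & !is.na(dev) & dev > cut] <- FALSE
    ray_target <- mask$vertices + ray_n * ifelse(is.finite(ray$t), ray$t, 0)
  }
  for (it in seq_len(cfg$num_iterations)) {
    if (is.null(ray_hit)) {
      cp <- cpp_closest_points(v, target$vertices, target$faces)
      r <- cp$distance
      med <- stats::median(r)
      madr <- stats::median(abs(r - med)) * 1.4826
      w <- as.numeric(r <= med + cfg$inlier_kappa * max(madr, 1e-12))
      if (cfg$trim > 0) {
        # scale-aware trimming: only residuals that are both in the
        # worst `trim` fraction and large relative to the typical
        # residual are dropped (truncation/hole territory), so near
        # convergence the whole surface keeps its pull
        cut <- max(stats::quantile(r, 1 - cfg$trim), 3 * med)
        w[r > cut] <- 0
      }
    } else {
      # validated ray hits are trusted correspondences with full
      # weight; misses (holes, truncation, rejected wrong-sheet hits)
      # carry no pull of their own and are interpolated by the
      # diffusion of their neighbours' displacements
      cp <- list(point = ray_target, distance = vnorm(ray_target - v))
      w <- as.numeric(ray_hit)
    }
    d <- (cp$point - v) * w
    wt <- w
    if (cfg$use_symmetric_correspondences) {
      # reverse pull: each target vertex attracts its nearest mask vertex
      nv <- cpp_knn(target$vertices, v, cfg$correspondence_k)
      rev_d <- matrix(0, n, 3); rev_w <- numeric(n)
      for (k in seq_len(ncol(nv$index))) {
        idx <- nv$index[, k]
        wk <- 1 / (nv$distance[, k] + 1e-9)
        pull <- (target$vertices - v[idx, , drop = FALSE]) * wk
        for (dd in 1:3)
          rev_d[, dd] <- rev_d[, dd] + tapply_add(pull[, dd], idx, n)
        rev_w <- rev_w + tapply_add(wk, idx, n)
      }
      has <- rev_w > 0
      rev_d[has, ] <- rev_d[has, , drop = FALSE] / rev_w[has]
      # average forward and reverse where both exist
      d <- d + rev_d * (rev_w > 0)
      wt <- wt + as.numeric(rev_w > 0)
      d[wt > 0, ] <- d[wt > 0, , drop = FALSE] / wt[wt > 0]
      wt <- as.numeric(wt > 0)
    }
    # diffuse the weighted field over the template graph; when every
    # vertex has a trusted ray target only the scalar field is needed
    if (is.null(ray_hit) || any(!ray_hit)) {
      df <- cpp_diffuse_field(d * wt, wt, nb$offs, nb$nbr, stiff[it])
      den <- df$den
      den[den <= 1e-12] <- 1
      disp <- df$num / den
    } else {
      disp <- matrix(0, n, 3)
    }
    if (!is.null(ray_hit)) {
      # for ray-hit vertices smooth only the scalar distance along the
      # ray: the direction field turns quickly across ridges and rims,
      # and averaging it as vectors would bend the template off its
      # rays exactly where the anatomy is most distinctive
      s_along <- rowSums(ray_n * (ray_target - v)) * ray_hit
      dfs <- cpp_diffuse_field(cbind(s_along * wt * ray_hit, 0, 0),
                               wt * ray_hit, nb$offs, nb$nbr, stiff[it])
      dens <- dfs$den
      dens[dens <= 1e-12] <- 1
      s_sm <- dfs$num[, 1] / dens
      disp[ray_hit, ] <- ray_n[ray_hit, , drop = FALSE] * s_sm[ray_hit]
    }
    if (!all(is.finite(disp)))
      stopf("non-finite displacement at non-rigid iteration %d", it)
    v <- v + disp
  }
  cp <- cpp_closest_points(v, target$vertices, target$faces)
  list(quasi = v,
       final_distance = mean(cp$distance[cp$distance <=
                               stats::quantile(cp$distance, 0.8)]))
}

#' Quality-control overlay for a registration
#'
#' Writes a QC image with orthographic front (x-y) and side (z-y)
#' views of the target with the masked shape superimposed, plus a
#' histogram of mask-to-target closest distances, and a JSON file of
#' distance statistics alongside. If no graphics device is available
#' the image is skipped with a warning and only the statistics are
#' written. Deterministic given its inputs.
#'
#' @param masked a [masked_shape()].
#' @param target the target [triangle_mesh()].
#' @param out_image_path output PNG path; a `.json` sibling is written
#'   next to it.
#' @return path of the JSON statistics file, invisibly.
#' @export
qc_overlay <- function(masked, target, out_image_path) {
  d <- cpp_closest_points(masked$quasi, target$vertices, target$faces)$distance
  stats_path <- sub("\\.[A-Za-z]+$", ".json", out_image_path)
  if (stats_path == out_image_path) stats_path <- paste0(out_image_path, ".json")
  st <- list(mean = mean(d), sd = stats::sd(d), median = stats::median(d),
             max = max(d), q95 = unname(stats::quantile(d, 0.95)),
             histogram = list(breaks = seq(0, max(d) + 1e-9, length.out = 33)))
  st$histogram$counts <- as.integer(table(cut(d, st$histogram$breaks,
                                              include.lowest = TRUE)))
  jsonlite::write_json(st, stats_path, digits = NA, auto_unbox = TRUE)
  ok <- tryCatch({
    grDevices::png(out_image_path, width = 1200, height = 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    tv <- target$vertices; mv <- masked$quasi
    graphics::plot(tv[, 1], tv[, 2], pch = ".", col = "grey50", asp = 1,
                   xlab = "x (mm)", ylab = "y (mm)", main = "front")
    graphics::points(mv[, 1], mv[, 2], pch = ".", col = "red")
    graphics::plot(tv[, 3], tv[, 2], pch = ".", col = "grey50", asp = 1,
                   xlab = "z (mm)", ylab = "y (mm)", main = "side")
    graphics::points(mv[, 3], mv[, 2], pch = ".", col = "red")
    graphics::hist(d, breaks = 32, main = "mask-to-target distance",
                   xlab = "distance (mm)")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("no graphics device available; wrote distance statistics only")
  invisible(stats_path)
}
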