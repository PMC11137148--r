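# Shared fixtures built in code. Sizes are kept small so the whole
# suite runs quickly; the synthetic generator provides realistic
# skull-like cases where geometry matters.

unit_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
}

unit_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

random_landmarks <- function(k = 11, seed = 1, scale = 50) {
  set.seed(seed)
  landmark_config(matrix(rnorm(k * 3, sd = scale), ncol = 3),
                  sprintf("L%02d", seq_len(k)))
}

# brute-force closest point on a mesh, independent of the package
# kernel: for every face, the candidates are the unconstrained
# in-plane minimizer (if inside the triangle), the exact projections
# onto the three edge segments, and the three vertices
brute_closest <- function(mesh, p) {
  seg_closest <- function(a, b) {
    t_ <- sum((p - a) * (b - a)) / sum((b - a)^2)
    a + min(1, max(0, t_)) * (b - a)
  }
  best <- Inf; bestpt <- NULL
  for (i in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    c_ <- mesh$vertices[mesh$faces[i, 3], ]
    e1 <- b - a; e2 <- c_ - a
    G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
    cand <- list(seg_closest(a, b), seg_closest(b, c_), seg_closest(c_, a))
    sol <- tryCatch(solve(G, rhs), error = function(e) NULL)
    if (!is.null(sol) && sol[1] >= 0 && sol[2] >= 0 && sum(sol) <= 1)
      cand[[length(cand) + 1]] <- a + sol[1] * e1 + sol[2] * e2
    for (q in cand) {
      dd <- sqrt(sum((q - p)^2))
      if (dd < best) { best <- dd; bestpt <- q }
    }
  }
  list(distance = best, point = bestpt)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent two-way ANOVA mean squares via stats::aov, for the ICC
# oracle
aov_mean_squares <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  list(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}
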