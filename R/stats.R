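#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: square root of
#' the summed squared distances of the points from their centroid.
#'
#' @param config K x 3 matrix or [landmark_config()].
#' @return centroid size in mm.
#' @export
centroid_size <- function(config) {
  m <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

#' Repeated-measures RMS dispersion
#'
#' Per-landmark root-mean-square distance of `R` repeated
#' configurations from their per-landmark mean — the intra-observer
#' (or automated-repeat) reliability measure. The mean RMS averages
#' over landmarks.
#'
#' @param configs list of R K x 3 matrices / [landmark_config()]s, or
#'   an R x K x 3 array.
#' @return list with `per_landmark` (named K-vector, mm) and `mean`
#'   (scalar mm).
#' @export
rms_repeat <- function(configs) {
  arr <- configs_to_array(configs)
  if (dim(arr)[1] < 2L) stopf("at least 2 repeated configurations required")
  ctr <- apply(arr, c(2, 3), mean)
  d2 <- apply(arr, 1, function(m) rowSums((m - ctr)^2))  # K x R
  per <- sqrt(rowMeans(d2))
  names(per) <- dimnames(arr)[[2]]
  list(per_landmark = per, mean = mean(per))
}

#' Between-group RMS distance
#'
#' Pairwise RMS distances between configurations (typically
#' per-observer means), per landmark and averaged — the inter-observer
#' reliability measure.
#'
#' @param configs list of K x 3 matrices / [landmark_config()]s (one
#'   per observer) with matching landmark names.
#' @return list with `per_landmark` (K-vector of mean pairwise RMS),
#'   `pairwise` (matrix of mean RMS per pair), and `mean`.
#' @export
rms_between <- function(configs) {
  arr <- configs_to_array(configs)
  g <- dim(arr)[1]
  if (g < 2L) stopf("at least 2 groups required")
  per <- matrix(0, dim(arr)[2], 0)
  pw <- matrix(NA_real_, g, g)
  acc <- NULL
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    d <- sqrt(rowSums((arr[i, , ] - arr[j, , ])^2))
    acc <- cbind(acc, d)
    pw[i, j] <- pw[j, i] <- sqrt(mean(d^2))
  }
  per_lm <- apply(acc, 1, function(x) sqrt(mean(x^2)))
  names(per_lm) <- dimnames(arr)[[2]]
  list(per_landmark = per_lm, pairwise = pw, mean = mean(per_lm))
}

configs_to_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) return(configs)
  mats <- lapply(configs, function(c_) {
    if (inherits(c_, "landmark_config")) c_$points else as.matrix(c_)
  })
  k <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == k)) stopf("configurations differ in K")
  nm1 <- rownames(mats[[1]])
  if (!is.null(nm1))
    for (m in mats) if (!identical(rownames(m), nm1))
      stopf("landmark names differ between configurations")
  arr <- array(NA_real_, c(length(mats), k, 3),
               dimnames = list(NULL, nm1, c("x", "y", "z")))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' Two-way single-measure intraclass correlation
#'
#' ICC from the two-way ANOVA decomposition of a subject x rater
#' matrix. `"two_way_consistency"` (ICC(C,1)) ignores systematic rater
#' bias; `"two_way_agreement"` (ICC(A,1)) penalizes it. 95% confidence
#' bounds follow the F-based formulas of McGraw & Wong (consistency
#' exactly, agreement via the Satterthwaite approximation).
#'
#' @param ratings n x k numeric matrix (n subjects, k raters), complete.
#' @param model `"two_way_agreement"` or `"two_way_consistency"`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `model`, `unit = "single"`, and the mean squares.
#' @export
icc <- function(ratings, model = c("two_way_agreement", "two_way_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (any(!is.finite(x))) stopf("ratings must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stopf("need at least 2 subjects and 2 raters")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((x - outer(rm_, cm, `+`) + gm)^2)
  if (ssr + ssc + sse < .Machine$double.eps)
    stopf("zero variance everywhere; ICC undefined")
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (model == "two_way_consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw & Wong (1996) approximate bounds for ICC(A,1)
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    fobs <- (a * msc + b * mse)
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * fobs) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - fobs) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  structure(list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
                 model = model, unit = "single", conf_level = conf_level,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single): %.4f  [%g%% CI %.4f - %.4f]\n",
              x$model, x$icc, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 95% limits of agreement
#' (`bias +/- 1.96 sd(diff)`) for paired measurements, with an
#' optional difference-vs-mean plot.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @param plot_path optional PNG path for the plot.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b, plot_path = NULL) {
  if (length(a) != length(b)) stopf("paired vectors differ in length")
  if (length(a) < 2L) stopf("need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  out <- list(bias = bias, loa_low = bias - 1.96 * s,
              loa_high = bias + 1.96 * s, sd_diff = s, n = length(a))
  if (!is.null(plot_path)) {
    ok <- tryCatch({
      grDevices::png(plot_path, width = 600, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::plot((a + b) / 2, d, xlab = "mean of methods",
                     ylab = "difference", main = "Bland-Altman")
      graphics::abline(h = c(out$bias, out$loa_low, out$loa_high),
                       lty = c(1, 2, 2), col = c("blue", "red", "red"))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      warning(sprintf("skipped Bland-Altman plot (%s)", ok))
  }
  out
}

#' Sequential ANOVA on centroid sizes
#'
#' Fixed-effects ANOVA with sequential (type-I) sums of squares, in the
#' layout of classic observer-study tables (Df, Sum Sq, Mean Sq,
#' F value, Pr(>F)). The formula names columns of `data`; factors are
#' coerced.
#'
#' @param data data frame with a numeric response (centroid size) and
#'   factor columns such as skull, observer, method, iteration.
#' @param formula model formula, e.g.
#'   `size ~ skull + observer + method + skull:observer`.
#' @return the `anova.lm` table (class `anova`).
#' @export
anova_centroid <- function(data, formula) {
  vars <- all.vars(formula)
  resp <- vars[1]
  for (v in vars[-1]) data[[v]] <- factor(data[[v]])
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("rank-deficient design; aliased terms: %s",
          paste(utils::head(al, 5), collapse = ", "))
  }
  if (stats::df.residual(fit) < 1) stopf("no residual degrees of freedom")
  stats::anova(fit)
}

#' Shape variance decomposition on Procrustes-aligned coordinates
#'
#' Sequential multivariate decomposition of the total Procrustes sum
#' of squares over the model factors: `R^2` of each factor is its
#' sequential SS (summed over all coordinates) divided by the total
#' SS. Significance is assessed by permutation of factor labels
#' (rows), seeded for reproducibility.
#'
#' @param aligned n x (3Q) matrix of flattened GPA-aligned coordinates
#'   (rows are shapes), or a [gpa()] object.
#' @param factors data frame of factors, rows matching shapes.
#' @param formula right-hand-side formula over `factors` columns, e.g.
#'   `~ skull + observer`. Default uses all columns sequentially.
#' @param n_perm permutations for p-values (default 999).
#' @param seed permutation seed.
#' @return data frame with columns `term`, `df`, `ss`, `r_squared`,
#'   `p_value` plus a `Residuals` row; attribute `ss_total`.
#' @export
shape_variance_decomposition <- function(aligned, factors, formula = NULL,
                                         n_perm = 999, seed = 1) {
  y <- flatten_shapes(aligned)
  factors <- as.data.frame(factors)
  if (nrow(factors) != nrow(y)) stopf("factor rows must match shapes")
  for (v in names(factors)) {
    factors[[v]] <- factor(factors[[v]])
    if (nlevels(factors[[v]]) < 2L)
      stopf("factor '%s' has a single level", v)
  }
  formula <- formula %||% stats::as.formula(
    paste("~", paste(names(factors), collapse = " + ")))
  terms_ <- attr(stats::terms(formula), "term.labels")
  decomp <- function(y, factors) {
    yc <- sweep(y, 2, colMeans(y))
    ss_tot <- sum(yc^2)
    fit_prev <- matrix(0, nrow(y), ncol(y))
    ss <- numeric(length(terms_)); df <- integer(length(terms_))
    rhs <- "1"
    for (i in seq_along(terms_)) {
      rhs <- paste(rhs, "+", terms_[i])
      mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), factors)
      qrm <- qr(mm)
      fit <- qr.fitted(qrm, yc)
      ss[i] <- sum((fit - fit_prev)^2)
      df[i] <- qrm$rank - (if (i == 1) 1L else sum(df[seq_len(i - 1)]) + 1L)
      fit_prev <- fit
    }
    list(ss = ss, df = df, ss_tot = ss_tot, ss_res = ss_tot - sum(ss))
  }
  obs <- decomp(y, factors)
  pvals <- rep(NA_real_, length(terms_))
  if (n_perm > 0) {
    exceed <- numeric(length(terms_))
    with_seed(seed, {
      for (p in seq_len(n_perm)) {
        perm <- sample.int(nrow(y))
        po <- decomp(y, factors[perm, , drop = FALSE])
        exceed <- exceed + (po$ss >= obs$ss - 1e-12)
      }
    })
    pvals <- (exceed + 1) / (n_perm + 1)
  }
  out <- data.frame(term = c(terms_, "Residuals"),
                    df = c(obs$df, nrow(y) - 1 - sum(obs$df)),
                    ss = c(obs$ss, obs$ss_res),
                    r_squared = c(obs$ss, obs$ss_res) / obs$ss_tot,
                    p_value = c(pvals, NA))
  attr(out, "ss_total") <- obs$ss_tot
  out
}

flatten_shapes <- function(x) {
  if (inherits(x, "gpa"))
    x <- t(vapply(x$aligned, as.vector, numeric(length(x$aligned[[1]]))))
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x))
    x <- t(vapply(x, function(m) as.vector(
      if (inherits(m, "masked_shape")) m$quasi else as.matrix(m)),
      numeric(length(as.matrix(if (inherits(x[[1]], "masked_shape")) x[[1]]$quasi
                               else x[[1]])))))
  as.matrix(x)
}

#' Remove covariate effects from shapes by partial least squares
#'
#' One-component-per-covariate PLS regression (NIPALS) of the flattened
#' shapes on the covariates; returns the residual shapes with the mean
#' shape added back. Constant covariates are dropped with a warning.
#'
#' @param shapes n x p matrix of flattened shape coordinates.
#' @param covariates data frame or matrix of numeric covariates.
#' @return matrix of adjusted shapes, same dimensions as input.
#' @export
residualize_covariates <- function(shapes, covariates) {
  y <- as.matrix(shapes)
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  keep <- apply(x, 2, function(c_) stats::sd(c_) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) return(y)
  ymean <- colMeans(y)
  yc <- sweep(y, 2, ymean)
  xc <- scale(x, center = TRUE, scale = TRUE)
  # one component per covariate: each (deflated) covariate is its own
  # latent score, its shape loading is regressed out, and remaining
  # covariates are deflated so shared variation is removed once
  for (j in seq_len(ncol(xc))) {
    t_ <- xc[, j]
    if (sum(t_^2) < 1e-12) next
    p_ <- as.vector(crossprod(yc, t_)) / sum(t_^2)
    yc <- yc - outer(t_, p_)
    if (j < ncol(xc)) {
      px <- as.vector(crossprod(xc, t_)) / sum(t_^2)
      xc <- xc - outer(t_, px)
    }
  }
  sweep(yc, 2, ymean, "+")
}

#' Principal component analysis of shape coordinates
#'
#' PCA of the covariance of aligned (optionally true-vertex-restricted)
#' flattened coordinates.
#'
#' @param shapes n x p matrix of flattened aligned coordinates, or a
#'   [gpa()] object.
#' @return object of class `shape_pca`: list with `eigenvalues`
#'   (non-increasing), `eigenvectors` (p x m), `scores` (n x m),
#'   `mean`, `var_explained`.
#' @export
shape_pca <- function(shapes) {
  y <- flatten_shapes(shapes)
  if (nrow(y) < 2L) stopf("need at least 2 shapes")
  pc <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, eigenvectors = pc$rotation,
                 scores = pc$x, mean = pc$center,
                 var_explained = ev / sum(ev)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(5, length(x$eigenvalues))
  cat(sprintf("shape_pca: %d shapes, %d coordinates\n",
              nrow(x$scores), length(x$mean)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(m), 100 * x$var_explained[seq_len(m)]),
            collapse = ", "), "\n")
  invisible(x)
}
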