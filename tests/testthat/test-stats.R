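test_that("centroid size matches its closed form", {
  expect_equal(centroid_size(matrix(c(5, 2, -1), 1)), 0)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sq * 3.7), 3.7 * sqrt(2), tolerance = 1e-12)
})

test_that("repeat RMS matches hand arithmetic and its sampling law", {
  # two rounds differing by 1 mm in x at one landmark: RMS = 0.5 there
  a <- matrix(0, 2, 3); b <- a; b[1, 1] <- 1
  r <- rms_repeat(list(a, b))
  expect_equal(unname(r$per_landmark), c(0.5, 0))
  expect_equal(r$mean, 0.25)
  expect_equal(rms_repeat(list(a, a, a))$mean, 0)
  expect_error(rms_repeat(list(a)), "at least 2")

  # iid sigma noise per axis: mean RMS -> sigma * sqrt(3 (R-1)/R)
  set.seed(12)
  sigma <- 0.8; R <- 3
  est <- replicate(40, {
    truth <- matrix(rnorm(60, sd = 20), 20, 3)
    rounds <- lapply(1:R, function(i) truth + matrix(rnorm(60, sd = sigma), 20, 3))
    rms_repeat(rounds)$mean
  })
  expect_equal(mean(est), sigma * sqrt(3 * (R - 1) / R), tolerance = 0.05)
})

test_that("inter-observer RMS sees offsets and orders observer skill", {
  truth <- matrix(rnorm(60, sd = 15), 20, 3)
  obsA <- truth; obsB <- truth; obsB[, 1] <- obsB[, 1] + 1
  r <- rms_between(list(obsA, obsB))
  expect_equal(unname(r$per_landmark), rep(1, 20), tolerance = 1e-12)
  expect_equal(r$mean, 1)
  expect_equal(rms_between(list(obsA, obsA, obsA))$mean, 0)

  # rigid motion of all configurations leaves both RMS measures alone
  R40 <- rotation_z(40)
  move <- function(m) m %*% t(R40) + 3
  expect_equal(rms_between(list(move(obsA), move(obsB)))$mean, r$mean,
               tolerance = 1e-9)
  r3 <- rms_repeat(list(obsA, obsB))
  expect_equal(rms_repeat(list(move(obsA), move(obsB)))$mean, r3$mean,
               tolerance = 1e-9)

  # simulated skill ordering recovered in nearly all replicates
  set.seed(77)
  hits <- replicate(60, {
    intra <- vapply(c(0.3, 0.6, 0.9), function(s) {
      rounds <- lapply(1:3, function(i) truth + matrix(rnorm(60, sd = s), 20, 3))
      rms_repeat(rounds)$mean
    }, 0)
    all(diff(intra) > 0)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("ICC matches an independent ANOVA oracle and its model semantics", {
  set.seed(8)
  m <- matrix(rnorm(18, sd = 2), 6, 3) + rnorm(6, sd = 10)

  # oracle: mean squares from stats::aov
  ms <- aov_mean_squares(m)
  n <- nrow(m); k <- ncol(m)
  expect_consistency <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  expect_agreement <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  expect_equal(icc(m, "two_way_consistency")$icc, expect_consistency,
               tolerance = 1e-12)
  expect_equal(icc(m, "two_way_agreement")$icc, expect_agreement,
               tolerance = 1e-12)

  # identical raters: ICC = 1
  ident <- matrix(rnorm(6, sd = 5), 6, 3)[, c(1, 1, 1)]
  expect_equal(icc(ident, "two_way_consistency")$icc, 1)

  # strong rater bias: consistency ~ 1, agreement clearly below
  subj <- rnorm(30, sd = 10)
  biased <- cbind(subj, subj + 5, subj - 5) + matrix(rnorm(90, sd = 0.01), 30)
  ic <- icc(biased, "two_way_consistency")
  ia <- icc(biased, "two_way_agreement")
  expect_gt(ic$icc, 0.999)
  expect_lt(ia$icc, 0.9)
  expect_lt(ia$icc, ic$icc)

  # confidence bounds bracket the estimate
  r <- icc(m, "two_way_agreement")
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
  expect_error(icc(matrix(1, 4, 3)), "zero variance")
})

test_that("Bland-Altman bias and limits are exact arithmetic", {
  a <- c(10, 12, 14, 16)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_high, 0)
  r <- bland_altman(a, a - 0.4)
  expect_equal(r$bias, 0.4, tolerance = 1e-12)
  set.seed(4)
  d <- rnorm(200)
  d <- (d - mean(d)) / sd(d)  # exact sd 1
  r2 <- bland_altman(d + 5, rep(5, 200))
  expect_equal(r2$loa_high - r2$bias, 1.96, tolerance = 1e-9)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("centroid-size ANOVA reproduces hand-computed sums of squares", {
  # 2x2 balanced design with known cell means, two replicates per cell
  d <- expand.grid(skull = factor(1:2), method = factor(c("m", "a")),
                   rep = 1:2)
  mu <- c(10, 14)[d$skull] + c(0, 2)[as.integer(d$method)]
  d$size <- mu
  tab <- suppressWarnings(anova_centroid(d, size ~ skull + method))
  # hand computation: SS_skull = 8 * (2)^2 = 32; SS_method = 8 * 1 = 8
  expect_equal(tab["skull", "Sum Sq"], 32, tolerance = 1e-9)
  expect_equal(tab["method", "Sum Sq"], 8, tolerance = 1e-9)
  expect_equal(tab["Residuals", "Sum Sq"], 0, tolerance = 1e-9)
  expect_equal(sum(tab[, "Df"]), nrow(d) - 1)

  # response depending only on skull: other factors get ~zero SS
  set.seed(6)
  d2 <- expand.grid(skull = factor(1:8), observer = factor(1:3))
  d2$size <- rnorm(8, sd = 10)[d2$skull]
  tab2 <- suppressWarnings(anova_centroid(d2, size ~ skull + observer))
  expect_lt(tab2["observer", "Sum Sq"], 1e-18 * tab2["skull", "Sum Sq"])

  # rank-deficient designs are refused with the aliased term named
  d3 <- data.frame(size = rnorm(6), skull = factor(c(1, 1, 2, 2, 3, 3)),
                   copy = factor(c(1, 1, 2, 2, 3, 3)))
  expect_error(anova_centroid(d3, size ~ skull + copy), "aliased")
})

test_that("ANOVA type-I error for a null method factor is calibrated", {
  set.seed(19)
  pvals <- replicate(500, {
    d <- expand.grid(skull = factor(1:10), observer = factor(1:3),
                     method = factor(c("m", "a")))
    d$size <- rnorm(10, sd = 8)[d$skull] + rnorm(nrow(d), sd = 1)
    anova_centroid(d, size ~ skull + observer + method)["method", "Pr(>F)"]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("shape variance decomposition recovers injected effects", {
  set.seed(30)
  n_skull <- 8; n_rep <- 3; p <- 30
  skull_eff <- matrix(rnorm(n_skull * p, sd = 4), n_skull)
  shapes <- do.call(rbind, lapply(seq_len(n_skull), function(s)
    matrix(rep(skull_eff[s, ], n_rep), n_rep, byrow = TRUE) +
      matrix(rnorm(n_rep * p, sd = 0.3), n_rep)))
  fac <- data.frame(skull = rep(seq_len(n_skull), each = n_rep))
  dec <- shape_variance_decomposition(shapes, fac, n_perm = 99, seed = 5)
  expect_gt(dec$r_squared[dec$term == "skull"], 0.95)
  expect_lt(dec$p_value[dec$term == "skull"], 0.05)
  # sums of squares partition the total exactly
  expect_equal(sum(dec$ss), attr(dec, "ss_total"), tolerance = 1e-9)

  # permuting labels leaves R^2 of a refit unchanged in distribution:
  # a null factor should get near-uniform p and tiny R^2
  fac$noise <- rep(1:3, n_skull)
  dec2 <- shape_variance_decomposition(shapes, fac,
                                       formula = ~ skull + noise,
                                       n_perm = 99, seed = 6)
  expect_lt(dec2$r_squared[dec2$term == "noise"], 0.05)
  expect_gt(dec2$p_value[dec2$term == "noise"], 0.05)
  expect_error(shape_variance_decomposition(shapes,
                                            data.frame(one = rep(1, nrow(shapes)))),
               "single level")
})

test_that("covariate residualization removes linear shape effects", {
  set.seed(9)
  n <- 40; p <- 24
  covar <- data.frame(age = rnorm(n, 40, 10), bmi = rnorm(n, 25, 3))
  beta <- rnorm(p)
  shapes <- outer(scale(covar$age)[, 1], beta) +
    matrix(rnorm(n * p, sd = 0.3), n)

  adj <- residualize_covariates(shapes, covar)
  # variance along the effect direction collapses
  proj <- function(m) as.numeric(m %*% beta / sqrt(sum(beta^2)))
  expect_lt(var(proj(adj)) / var(proj(shapes)), 0.05)
  # refit slope on the covariate is ~ zero
  slope <- coef(lm(proj(adj) ~ covar$age))[2]
  expect_lt(abs(slope), 0.02)

  # uncorrelated covariate leaves shapes essentially untouched
  pure <- matrix(rnorm(n * p), n)
  adj2 <- residualize_covariates(pure, data.frame(z = rnorm(n)))
  expect_lt(mean(abs(adj2 - pure)), 0.15)

  expect_warning(residualize_covariates(pure, data.frame(k = rep(2, n))),
                 "constant")
})

test_that("shape PCA reconstructs and ranks variance", {
  set.seed(14)
  base <- rnorm(30)
  mode <- rnorm(30)
  shapes <- t(vapply(rnorm(12, sd = 3), function(s)
    base + s * mode + rnorm(30, sd = 0.05), numeric(30)))
  pc <- shape_pca(shapes)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_gt(pc$var_explained[1], 0.95)
  # full reconstruction is exact
  rec <- sweep(pc$scores %*% t(pc$eigenvectors), 2, pc$mean, "+")
  expect_lt(max(abs(rec - shapes)), 1e-9)
  # two shapes give exactly one positive eigenvalue
  two <- shape_pca(shapes[1:2, ])
  expect_equal(sum(two$eigenvalues > 1e-12), 1L)
})
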