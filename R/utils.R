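#' @useDynLib densecranio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov anova lm pf qf rnorm runif sd var prcomp median quantile complete.cases
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. All package
# randomness flows through this helper; no hidden global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

as_point_matrix <- function(x, what = "points") {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) == 1L) x <- matrix(as.numeric(x), ncol = 3)
  if (ncol(x) != 3L) stopf("%s must be an n x 3 matrix", what)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stopf("%s contain non-finite coordinates", what)
  x
}

vnorm <- function(x) sqrt(rowSums(x^2))

normalize_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}
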