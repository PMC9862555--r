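#' @importFrom stats approx density dnorm mad median pnorm qchisq qnorm
#'   quantile rbinom rlnorm rnorm runif rexp rpois sd setNames coef glm
#'   binomial predict vcov plogis qlogis uniroot mahalanobis
#' @importFrom utils modifyList head tail
#' @importFrom mclust Mclust mclustBIC
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  seed = NULL runs under the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying within 32-bit integer range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + 7919 * k) %% 2147483647)
}

# Vectorised even-odd (ray casting) point-in-polygon test.  Points exactly on
# an edge count as inside, matching the closed-gate boundary convention.
pointsInPolygon <- function(x, y, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L)
  n <- length(x)
  inside <- logical(n)
  on_edge <- logical(n)
  px <- poly[, 1L]; py <- poly[, 2L]
  nv <- length(px)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # edge hit: collinear and within bounding box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on <- abs(cross) <= 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Subsample row indices for expensive model fits; deterministic under seed.
fitSubsample <- function(n, max_n, seed = NULL) {
  if (n <= max_n) return(seq_len(n))
  withSeed(seed, sort(sample.int(n, max_n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
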