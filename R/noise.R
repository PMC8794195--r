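#' Seeded noise generators for calibration standards
#'
#' Monte Carlo calibration of the Sevcik dimension requires reference
#' sequences with known limiting fractal dimension: i.i.d. ("white") noise
#' (limit dimension 2) and Brownian random walks (limit dimension 1.5).
#' A Cauchy generator is included to exercise the nonparametric toolbox on
#' a heavy-tailed law without moments. All generators consume one seeded
#' Mersenne-Twister uniform stream per call; the same seed always yields
#' the same sequence, and the caller's RNG state is left untouched.
#'
#' Gaussian deviates are produced by the Box-Muller transform with both
#' branches (sine and cosine) consumed in order, so a stream of n deviates
#' uses exactly ceiling(n/2) uniform pairs.
#'
#' @name noise-generators
NULL

# Run expr with a private RNG stream; restores the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a component seed from a master seed
#'
#' One master seed drives every stochastic stage of an analysis; each
#' component uses `master + offset` (kept within 32-bit integer range) so
#' streams are reproducible and never shared between components.
#'
#' @param master integer master seed.
#' @param offset small non-negative integer, one per component.
#' @return an integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.double(master) + as.double(offset)) %% 2147483647)
}

#' @describeIn noise-generators Uniform U[a, b] deviates.
#' @param n number of points (>= 1; >= 2 for `gen_brownian`).
#' @param a,b interval bounds, a < b.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @export
gen_uniform <- function(n, a = 0, b = 1, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1)
  if (!(a < b)) stop("uniform interval requires a < b (got a = ", a,
                     ", b = ", b, ")")
  with_seed(seed, a + (b - a) * stats::runif(n))
}

#' Box-Muller transform of one uniform pair
#'
#' Maps two independent U(0, 1] variates to two independent N(0, 1)
#' variates: the sine branch sin(2*pi*r1)*sqrt(-2*log(r2)) and the cosine
#' branch cos(2*pi*r1)*sqrt(-2*log(r2)).
#'
#' @param r1,r2 uniform variates in (0, 1].
#' @return numeric length 2: c(sine branch, cosine branch).
#' @export
box_muller <- function(r1, r2) {
  stopifnot(r1 >= 0, r1 <= 1, r2 > 0, r2 <= 1)
  r <- sqrt(-2 * log(r2))
  c(sin(2 * pi * r1) * r, cos(2 * pi * r1) * r)
}

#' @describeIn noise-generators Gaussian N(mean, sd^2) deviates via
#'   Box-Muller; both branches consumed in order.
#' @param mean,sd Gaussian location and scale; sd > 0.
#' @export
gen_gaussian <- function(n, mean = 0, sd = 1, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1)
  if (sd <= 0) stop("Gaussian scale must be positive (got sd = ", sd, ")")
  with_seed(seed, {
    m <- ceiling(n / 2)
    r1 <- stats::runif(m)
    r2 <- stats::runif(m)
    r2[r2 == 0] <- .Machine$double.xmin  # log(0) guard
    r <- sqrt(-2 * log(r2))
    z <- as.vector(rbind(sin(2 * pi * r1) * r, cos(2 * pi * r1) * r))[seq_len(n)]
    mean + sd * z
  })
}

#' @describeIn noise-generators Brownian walk: b[1] = 0,
#'   b[i] = b[i-1] + g[i-1] with g ~ N(0, sd^2). `sd = 0` degenerates to
#'   the all-zero sequence.
#' @export
gen_brownian <- function(n, sd = 1, seed = NULL) {
  stopifnot(length(n) == 1L)
  if (n < 2) stop("a walk needs at least 2 points")
  if (sd < 0) stop("negative increment scale")
  if (sd == 0) return(numeric(n))
  c(0, cumsum(gen_gaussian(n - 1, 0, sd, seed = seed)))
}

#' @describeIn noise-generators Cauchy deviates by inversion of the
#'   closed-form distribution function; location is the median, scale > 0.
#' @param location,scale Cauchy median and dispersion; scale > 0.
#' @export
gen_cauchy <- function(n, location = 0, scale = 1, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1)
  if (scale <= 0) stop("Cauchy scale must be positive (got ", scale, ")")
  with_seed(seed, cauchy_quantile(stats::runif(n), location, scale))
}
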