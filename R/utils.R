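#' @useDynLib othg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd qt pt median setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package take an explicit `seed` and run
#' under this helper, so a fixed seed gives identical output without
#' disturbing the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) v else v / n
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}

#' Gaussian blur of a 3D volume (separable, reflect padding)
#'
#' @param a numeric 3D array.
#' @param sigma standard deviation in voxels, length 1 (isotropic in voxel
#'   units) or 3 in (z,y,x) order. A zero entry skips that axis.
#' @return blurred array of the same shape.
#' @export
gaussian_blur3 <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(a)
  out <- a
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- cpp_conv_axis(out, as.integer(d), k, ax - 1L)
  }
  out
}

box_filter3 <- function(a, radius, op = c("max", "min")) {
  op <- match.arg(op)
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  d <- dim(a)
  out <- a
  for (ax in 1:3) {
    r <- as.integer(radius[ax])
    if (r <= 0) next
    out <- cpp_minmax_axis(out, as.integer(d), r, ax - 1L, op == "max")
  }
  out
}

#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximization on a fixed-bin histogram.
#' Used as the default automatic threshold in colocalization and
#' semi-automatic segmentation.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values for Otsu threshold")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(n_bins, 1L + floor((x - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}
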