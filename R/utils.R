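`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded phantom generation never
#' perturbs user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed below 2^31 from a base seed and a stream label
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729 + 17) %% 2147483647
}

#' 1-D Gaussian kernel (unit sum) for separable convolution
#' @param sigma Standard deviation in voxels.
#' @param truncate Kernel half-width in sigmas (default 3).
#' @keywords internal
gaussian_kernel_1d <- function(sigma, truncate = 3) {
  if (sigma < 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

conv_sep3 <- function(a, kz = NULL, ky = NULL, kx = NULL) {
  d <- dim(a)
  stopifnot(length(d) == 3)
  out <- a
  for (ax in 0:2) {
    k <- list(kz, ky, kx)[[ax + 1]]
    if (!is.null(k) && length(k) > 1)
      out <- cpp_conv_axis(out, d, as.numeric(k), ax)
  }
  dim(out) <- d
  out
}

norm01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || diff(r) == 0) return(array(0, dim(x)))
  (x - r[1]) / diff(r)
}

#' Otsu threshold of an intensity array
#'
#' Histogram-based between-class variance maximization; used to initialize
#' the manual pore-segmentation threshold.
#'
#' @param x Numeric array or vector.
#' @param nbins Number of histogram bins.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x[is.finite(x)])
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(v, breaks = seq(r[1], r[2], length.out = nbins + 1L), plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, length(p))
  sb[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(sb)]
}

#' First time at which a series reaches its (plateau-tolerant) maximum
#'
#' @param x Numeric series.
#' @param times Time stamps matching `x`.
#' @param tol Plateau tolerance (fraction of the series range) absorbing numerical ties.
#' @return Time of the detected peak.
#' @export
peak_time <- function(x, times, tol = 0.01) {
  stopifnot(length(x) == length(times))
  rng <- diff(range(x, na.rm = TRUE))
  thr <- max(x, na.rm = TRUE) - tol * rng
  times[which(x >= thr)[1]]
}

#' Estimate a pulse period from a time series by autocorrelation
#'
#' Removes the slow colonization trend (loess), then locates the first local
#' maximum of the autocorrelation function at positive lag.
#'
#' @param x Series of densities.
#' @param dt Sampling interval (h).
#' @param max_lag Largest lag (in samples) to consider.
#' @param span Loess span of the trend removed before the autocorrelation.
#' @return Estimated period in the units of `dt`, or NA when no interior peak.
#' @export
estimate_pulse_period <- function(x, dt = 1, max_lag = min(10L, length(x) - 2L),
                                  span = 0.5) {
  t <- seq_along(x)
  res <- x - stats::predict(stats::loess(x ~ t, span = span))
  ac <- stats::acf(res, lag.max = max_lag, plot = FALSE)$acf[-1]
  if (length(ac) < 3) return(NA_real_)
  loc <- which(diff(sign(diff(ac))) == -2) + 1  # interior local maxima
  if (!length(loc)) loc <- which.max(ac)
  loc[1] * dt
}

pearson <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok])
}

#' Intensity-weighted centroid of an array region (voxel coordinates, 1-based)
#' @keywords internal
weighted_centroid <- function(a) {
  d <- dim(a)
  idx <- which(a > 0)
  if (!length(idx)) return(rep(NA_real_, 3))
  w <- a[idx]
  z <- (idx - 1) %% d[1] + 1
  y <- ((idx - 1) %/% d[1]) %% d[2] + 1
  x <- (idx - 1) %/% (d[1] * d[2]) + 1
  c(sum(z * w), sum(y * w), sum(x * w)) / sum(w)
}
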