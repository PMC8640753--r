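# Independent brute-force oracles and tiny scene builders used across tests.

# Squared Euclidean distance from every voxel to the nearest feature voxel,
# computed by exhaustive per-axis expansion (no transform algorithm shared
# with the implementation).
edt2_bruteforce <- function(feature, spacing) {
  d <- dim(feature)
  sp <- rep_len(spacing, 3)
  vox <- arrayInd(seq_len(prod(d)), d)
  fe <- which(feature, arr.ind = TRUE)
  if (!nrow(fe)) return(array(Inf, d))
  dd <- outer(vox[, 1] * sp[1], fe[, 1] * sp[1], "-")^2 +
        outer(vox[, 2] * sp[2], fe[, 2] * sp[2], "-")^2 +
        outer(vox[, 3] * sp[3], fe[, 3] * sp[3], "-")^2
  array(apply(dd, 1, min), d)
}

edt_bruteforce <- function(feature, spacing) sqrt(edt2_bruteforce(feature, spacing))

# Exhaustive local thickness: for every pore voxel, the largest inscribed
# sphere (centred at any pore voxel, radius = distance to nearest solid voxel
# centre or virtual border background) containing it.
lt_bruteforce <- function(pore, spacing) {
  d <- dim(pore)
  sp <- rep_len(spacing, 3)
  idx <- arrayInd(seq_len(prod(d)), d)
  border2 <- pmin(idx[, 1] * sp[1], (d[1] - idx[, 1] + 1) * sp[1],
                  idx[, 2] * sp[2], (d[2] - idx[, 2] + 1) * sp[2],
                  idx[, 3] * sp[3], (d[3] - idx[, 3] + 1) * sp[3])^2
  solid2 <- if (any(!pore)) as.vector(edt2_bruteforce(!pore, sp)) else rep(Inf, prod(d))
  R2 <- pmin(solid2, border2)
  R2[!pore] <- 0
  pi_ <- which(as.vector(pore))
  out <- numeric(prod(d))
  if (length(pi_)) {
    P <- idx[pi_, , drop = FALSE]
    dd <- outer(P[, 1] * sp[1], P[, 1] * sp[1], "-")^2 +
          outer(P[, 2] * sp[2], P[, 2] * sp[2], "-")^2 +
          outer(P[, 3] * sp[3], P[, 3] * sp[3], "-")^2
    ok <- dd <= matrix(R2[pi_] + 1e-9, length(pi_), length(pi_), byrow = TRUE)
    diam <- matrix(2 * sqrt(R2[pi_]), length(pi_), length(pi_), byrow = TRUE)
    diam[!ok] <- 0
    out[pi_] <- apply(diam, 1, max)
  }
  array(out, dim = d)
}

# solid ball mask on a voxel grid (1-based centre, radius in voxels)
ball_mask <- function(dims, center, radius) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  m <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
       (idx[, 3] - center[3])^2 <= radius^2
  array(m, dims)
}

# axis-aligned bright cylinder along y
cylinder_mask <- function(dims, center_zx, radius, ylim) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  m <- (idx[, 1] - center_zx[1])^2 + (idx[, 3] - center_zx[2])^2 <= radius^2 &
    idx[, 2] >= ylim[1] & idx[, 2] <= ylim[2]
  array(m, dims)
}

# linear FWHM of a 1-D profile by interpolated half-maximum crossings
profile_fwhm <- function(x, spacing = 1) {
  half <- max(x) / 2
  above <- which(x >= half)
  i1 <- min(above); i2 <- max(above)
  left <- if (i1 > 1) i1 - (x[i1] - half) / (x[i1] - x[i1 - 1]) else i1
  right <- if (i2 < length(x)) i2 + (x[i2] - half) / (x[i2] - x[i2 + 1]) else i2
  (right - left) * spacing
}

# small single-channel truth volume with a few bright balls; returns the
# volume and the ball centres (voxel coordinates)
balls_truth <- function(dims = c(24L, 40L, 24L), n = 5, radius = 2, seed = 5,
                        voxel_um = 50, channel = "particle", min_sep = 11) {
  set.seed(seed)
  centers <- matrix(numeric(0), 0, 3)
  while (nrow(centers) < n) {
    p <- c(sample(6:(dims[1] - 6), 1), sample(6:(dims[2] - 6), 1),
           sample(6:(dims[3] - 6), 1))
    if (!nrow(centers) || min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep)
      centers <- rbind(centers, p)
  }
  a <- array(0, dims)
  for (i in seq_len(n)) a <- a | ball_mask(dims, centers[i, ], radius)
  ch <- list(600 * a)
  names(ch) <- channel
  list(volume = volume_image(ch, voxel_um), centers = centers)
}

expect_same_array <- function(a, b, tol = 1e-9) {
  expect_equal(as.vector(a), as.vector(b), tolerance = tol)
}
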