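# ---- image pyramids -------------------------------------------------------

pyr_kernel <- c(1, 4, 6, 4, 1) / 16

as_arr3 <- function(a) if (length(dim(a)) == 2) array(a, c(dim(a), 1L)) else a

down_nd <- function(a) {
  d <- dim(a)
  s <- conv_sep3(a, pyr_kernel, pyr_kernel, if (d[3] > 1) pyr_kernel else NULL)
  s[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
}

up_nd <- function(a, target) {
  d <- dim(a)
  iz <- seq(1, target[1], 2)[seq_len(d[1])]
  iy <- seq(1, target[2], 2)[seq_len(d[2])]
  ix <- seq(1, target[3], 2)[seq_len(d[3])]
  z <- array(0, target); z[iz, iy, ix] <- a
  m <- array(0, target); m[iz, iy, ix] <- 1
  kx <- if (target[3] > 1) 2 * pyr_kernel else NULL
  num <- conv_sep3(z, 2 * pyr_kernel, 2 * pyr_kernel, kx)
  # normalize by the interpolated sampling mask so boundaries stay exact
  den <- conv_sep3(m, 2 * pyr_kernel, 2 * pyr_kernel, kx)
  num / pmax(den, 1e-12)
}

pyr_gauss <- function(a, levels) {
  out <- list(a)
  for (l in seq_len(levels - 1)) out[[l + 1]] <- down_nd(out[[l]])
  out
}

pyr_laplace <- function(G) {
  L <- length(G)
  lap <- vector("list", L)
  if (L > 1) for (l in seq_len(L - 1)) lap[[l]] <- G[[l]] - up_nd(G[[l + 1]], dim(G[[l]]))
  lap[[L]] <- G[[L]]
  lap
}

pyr_collapse <- function(lap) {
  L <- length(lap)
  R <- lap[[L]]
  if (L > 1) for (l in rev(seq_len(L - 1))) R <- up_nd(R, dim(lap[[l]])) + lap[[l]]
  R
}

max_levels <- function(d) max(1L, floor(log2(max(2L, min(d[d > 1])))) - 1L)

# ---- shear correction -----------------------------------------------------

#' Correct the 45-degree scan shear of a raw tile stack
#'
#' Applies the inverse shear with nearest-neighbour interpolation, producing
#' an axis-aligned single-channel volume on a grid with z spacing
#' `slice_step * cos(theta)` and in-plane spacing equal to the camera pixel.
#' Voxels never observed by the pass (the sheared corners) are `NA`.
#'
#' @param tile A [tile_stack()].
#' @return A single-channel [volume_image()].
#' @export
shear_correct <- function(tile) {
  stopifnot(inherits(tile, "tile_stack"))
  if (is.null(tile$scan_angle_deg) || !is.finite(tile$scan_angle_deg))
    stop("metadata error: missing or invalid scan angle")
  th <- tile$scan_angle_deg * pi / 180
  h <- tile$pixel_size_um
  shear_vox <- tile$slice_step_um * sin(th) / h
  dz_um <- tile$slice_step_um * cos(th)
  d <- dim(tile$frames)
  Hout <- d[2] + as.integer(ceiling((d[1] - 1) * shear_vox))
  arr <- cpp_unshear(tile$frames, d, shear_vox, Hout)
  dim(arr) <- c(d[1], Hout, d[3])
  ch <- list(arr)
  names(ch) <- tile$channel
  volume_image(ch, voxel_size_um = c(dz_um, h, h), origin_um = tile$origin_um,
               timepoint_h = tile$timepoint_h)
}

# ---- flat-field -----------------------------------------------------------

collect_frames <- function(x) {
  if (inherits(x, "tile_stack")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "tile_stack")) {
    mats <- do.call(c, lapply(x, function(t)
      lapply(seq_len(dim(t$frames)[1]), function(k) t$frames[k, , ])))
    x <- mats
  }
  if (is.list(x) && length(x) && is.matrix(x[[1]])) {
    d <- dim(x[[1]])
    x <- array(unlist(x, use.names = FALSE), c(d, length(x)))
  }
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  x
}

#' Estimate a flat-field correction from the mode of a frame dataset
#'
#' Soil is a textured material: the repeating particle structure makes the
#' modal pixel intensity spatially stationary, so the per-pixel histogram
#' mode over a whole dataset (within a small neighbourhood) estimates the
#' illumination/detection vignetting. The weight matrix is the global
#' reference mode divided by the local mode, clipped to \[0.2, 5\]. Values in
#' the lowest `background_exclude_frac` of the dynamic range (the unstained
#' pore space) are excluded from the histograms.
#'
#' @param frames A 3-D array (row, col, frame), a list of matrices, or (a
#'   list of) [tile_stack()] objects.
#' @param neighborhood_px Width of the square pixel neighbourhood.
#' @param bin_width Histogram bin width (default 1/256 of the dynamic range).
#' @param clip Weight clipping range.
#' @param background_exclude Background exclusion rule: `"otsu"` (default)
#'   drops values below the Otsu split so the stained-particle population
#'   dominates the histograms; a number in \[0, 1) drops that fraction of the
#'   dynamic range; 0 disables exclusion.
#' @return An object of class `flatfield_model`.
#' @export
estimate_flatfield <- function(frames, neighborhood_px = 9L, bin_width = NULL,
                               clip = c(0.2, 5), background_exclude = "otsu") {
  fr <- collect_frames(frames)
  rng <- range(fr, na.rm = TRUE)
  if (!all(is.finite(rng)) || (diff(rng) == 0 && rng[1] == 0))
    stop("estimation error: degenerate constant-zero dataset")
  d <- dim(fr)
  if (diff(rng) == 0) {
    return(structure(list(weight_matrix = matrix(1, d[1], d[2]),
                          mode_reference = rng[1],
                          neighborhood_px = neighborhood_px, bin_width = 0,
                          clip = clip), class = "flatfield_model"))
  }
  bw <- bin_width %||% (diff(rng) / 256)
  nbins <- max(2L, as.integer(ceiling(diff(rng) / bw)))
  excl <- if (identical(background_exclude, "otsu")) otsu_threshold(fr)
          else if (is.numeric(background_exclude) && background_exclude > 0)
            rng[1] + background_exclude * diff(rng)
          else -Inf
  local_mode <- cpp_local_mode(fr, d, max(0L, neighborhood_px %/% 2L),
                               nbins, rng[1], rng[2], excl)
  v <- fr[fr >= excl & is.finite(fr)]
  b <- pmin(nbins - 1L, pmax(0L, floor((v - rng[1]) / bw)))
  ref <- rng[1] + (which.max(tabulate(b + 1L, nbins)) - 0.5) * bw
  w <- ref / local_mode
  w[!is.finite(w)] <- 1
  w <- pmin(pmax(w, clip[1]), clip[2])
  structure(list(weight_matrix = w, mode_reference = ref,
                 neighborhood_px = neighborhood_px, bin_width = bw, clip = clip),
            class = "flatfield_model")
}

# Band-wise multiplicative correction: the frame is decomposed into a
# Laplacian pyramid, each band (optionally attenuated by a per-level gain) is
# reconstructed to full resolution and corrected with the weight field there.
# With unit band gains this equals plain multiplication by the weights.
pyramid_multiply <- function(f, w, levels, level_gains = NULL) {
  if (levels <= 1) return(f * w)
  f3 <- as_arr3(f)
  levels <- min(levels, max_levels(dim(f3)))
  if (levels <= 1) return(f * w)
  lap <- pyr_laplace(pyr_gauss(f3, levels))
  g <- rep_len(level_gains %||% 1, levels)
  acc <- lap[[levels]] * g[levels]
  for (l in rev(seq_len(levels - 1))) acc <- up_nd(acc, dim(lap[[l]])) + lap[[l]] * g[l]
  out <- acc * as_arr3(w)
  if (is.matrix(f)) out[, , 1] else array(out, dim(f))
}

#' Apply a flat-field model to frames or a volume
#'
#' Multiplicative correction applied per Laplacian-pyramid level and
#' reconstructed (`pyramid_levels = 1` is exact per-pixel multiplication).
#'
#' @param x A [tile_stack()] (corrected per camera frame) or a
#'   [volume_image()] (corrected per z-slice).
#' @param model A [estimate_flatfield()] result.
#' @param pyramid_levels Pyramid depth.
#' @param level_gains Optional per-level band gains (coarse-to-fine recycling;
#'   default 1 for every band, which makes the correction exactly
#'   multiplicative).
#' @return Object of the same class as `x`, intensities >= 0.
#' @export
apply_flatfield <- function(x, model, pyramid_levels = 3L, level_gains = NULL) {
  w <- model$weight_matrix
  fix <- function(fr) {
    if (!identical(dim(fr), dim(w)))
      stop(sprintf("shape mismatch: frame %s vs weight matrix %s",
                   paste(dim(fr), collapse = "x"), paste(dim(w), collapse = "x")))
    pmax(pyramid_multiply(fr, w, pyramid_levels, level_gains), 0)
  }
  if (inherits(x, "tile_stack")) {
    for (k in seq_len(dim(x$frames)[1])) x$frames[k, , ] <- fix(x$frames[k, , ])
    return(x)
  }
  if (inherits(x, "volume_image")) {
    x$channels <- lapply(x$channels, function(a) {
      for (z in seq_len(dim(a)[1])) a[z, , ] <- fix(a[z, , ])
      a
    })
    return(x)
  }
  stop("x must be a tile_stack or volume_image")
}

# ---- PSF and deconvolution ------------------------------------------------

#' Separable Gaussian light-sheet point spread function
#'
#' Axial (z) sigma from the sheet thickness FWHM, lateral (y, x) sigma from
#' the in-plane FWHM, truncated at 3 sigma and normalized to unit sum.
#'
#' @param optics An [optics_model()].
#' @param voxel_size_um Voxel size, scalar or (z, y, x).
#' @return An object of class `lightsheet_psf` with the 3-D `kernel` and its
#'   separable 1-D factors.
#' @export
make_lightsheet_psf <- function(optics, voxel_size_um) {
  vs <- rep_len(as.numeric(voxel_size_um), 3)
  if (optics$sheet_fwhm_um < vs[1] || optics$lateral_fwhm_um < max(vs[2:3]))
    stop(sprintf("undersampling error: PSF FWHM (%g/%g um) below voxel size (%s um)",
                 optics$sheet_fwhm_um, optics$lateral_fwhm_um,
                 paste(vs, collapse = "/")))
  fwhm2sig <- 1 / (2 * sqrt(2 * log(2)))
  kz <- gaussian_kernel_1d(optics$sheet_fwhm_um * fwhm2sig / vs[1])
  ky <- gaussian_kernel_1d(optics$lateral_fwhm_um * fwhm2sig / vs[2])
  kx <- gaussian_kernel_1d(optics$lateral_fwhm_um * fwhm2sig / vs[3])
  kernel <- outer(outer(kz, ky), kx)
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, sep = list(kz = kz, ky = ky, kx = kx),
                 sheet_fwhm_um = optics$sheet_fwhm_um,
                 lateral_fwhm_um = optics$lateral_fwhm_um,
                 voxel_size_um = vs),
            class = "lightsheet_psf")
}

#' Ideal (delta) point spread function
#' @export
psf_delta <- function() {
  structure(list(kernel = array(1, c(1, 1, 1)), sep = list(kz = 1, ky = 1, kx = 1),
                 sheet_fwhm_um = 0, lateral_fwhm_um = 0, voxel_size_um = c(1, 1, 1)),
            class = "lightsheet_psf")
}

#' Richardson-Lucy deconvolution with a light-sheet PSF
#'
#' Standard multiplicative maximum-likelihood updates for Poisson noise.
#' The estimate stays non-negative and, with a normalized PSF and reflective
#' edge handling, conserves total intensity; the Poisson likelihood of the
#' blurred estimate is non-decreasing across iterations.
#'
#' @param volume A [volume_image()] (all channels deconvolved) or array.
#' @param psf A [make_lightsheet_psf()] result.
#' @param iterations Number of RL iterations (>= 1).
#' @param track_likelihood Record the Poisson log-likelihood per iteration in
#'   attribute `"loglik"`.
#' @return Same type as `volume`.
#' @export
lr_deconvolve <- function(volume, psf, iterations = 10L, track_likelihood = FALSE) {
  stopifnot(iterations >= 1)
  deconv1 <- function(data) {
    nas <- is.na(data)
    data[nas] <- 0
    if (min(data) < 0) stop("validation error: negative input voxels")
    eps <- 1e-12 * max(data, 1e-300)
    est <- data
    ll <- numeric(0)
    for (it in seq_len(iterations)) {
      blur <- conv_sep3(est, psf$sep$kz, psf$sep$ky, psf$sep$kx)
      if (track_likelihood)
        ll <- c(ll, sum(data * log(pmax(blur, eps)) - blur))
      ratio <- data / pmax(blur, eps)
      est <- est * conv_sep3(ratio, psf$sep$kz, psf$sep$ky, psf$sep$kx)
    }
    est[nas] <- NA_real_
    if (track_likelihood) attr(est, "loglik") <- ll
    est
  }
  if (inherits(volume, "volume_image")) return(map_channels(volume, deconv1))
  deconv1(volume)
}

# ---- stitching ------------------------------------------------------------

feather_weight <- function(valid) {
  d <- dim(valid)
  pd <- d + 2L
  padded <- array(TRUE, pd)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !valid
  w <- cpp_edt(padded, pd, c(1, 1, 1))
  dim(w) <- pd
  w <- w[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  w[!valid] <- 0
  # squared ramp keeps smoothed coarse-level weights near zero at the data
  # boundary, limiting leakage of extrapolated fill content
  w^2
}

#' Stitch shear-corrected tiles into one volume
#'
#' Tiles are first refined by integer-shift cross-correlation registration in
#' their overlap zones (search radius `search_radius` voxels), then fused by
#' multi-level Laplacian-pyramid blending with distance-feathered weights.
#' Tiles are processed in a canonical origin order, so the result does not
#' depend on input order.
#'
#' @param tiles List of [volume_image()] tiles sharing voxel size and channel
#'   set.
#' @param search_radius Registration search radius in voxels (0 disables).
#' @param register_channel Channel used for registration (default: first).
#' @param pyramid_levels Blend depth; default
#'   `floor(log2(min overlap extent)) - 1`, at least 1.
#' @return A [volume_image()] covering the union of tiles (`NA` where no tile
#'   has data).
#' @export
stitch_tiles <- function(tiles, search_radius = 5L, register_channel = NULL,
                         pyramid_levels = NULL) {
  stopifnot(length(tiles) >= 1)
  if (length(tiles) == 1) return(tiles[[1]])
  vs <- tiles[[1]]$voxel_size_um
  for (t in tiles) if (max(abs(t$voxel_size_um - vs)) > 1e-9)
    stop("tiles must share a voxel size")
  ord <- order(vapply(tiles, function(t) t$origin_um[1], 0),
               vapply(tiles, function(t) t$origin_um[2], 0),
               vapply(tiles, function(t) t$origin_um[3], 0))
  tiles <- tiles[ord]
  chn <- names(tiles[[1]]$channels)
  # registration needs texture: prefer the particle channel when present
  rch <- register_channel %||% (if ("particle" %in% chn) "particle" else chn[1])
  offs <- function() {
    o0 <- apply(do.call(rbind, lapply(tiles, `[[`, "origin_um")), 2, min)
    lapply(tiles, function(t) {
      o <- (t$origin_um - o0) / vs
      if (max(abs(o - round(o))) > 1e-6) stop("tile origins must lie on the voxel lattice")
      as.integer(round(o))
    })
  }
  dims <- lapply(tiles, vol_dim)
  # overlap bounding box (1-based index ranges on the global grid) of tiles i, j
  overlap_box <- function(off, i, j) {
    lo <- pmax(off[[i]], off[[j]]) + 1L
    hi <- pmin(off[[i]] + dims[[i]], off[[j]] + dims[[j]])
    if (any(hi < lo)) NULL else rbind(lo, hi)
  }
  if (search_radius > 0 && length(tiles) > 1) {
    off <- offs()
    for (t in 2:length(tiles)) {
      best <- NULL; bestvol <- 0
      for (p in 1:(t - 1)) {
        bx <- overlap_box(off, p, t)
        if (is.null(bx)) next
        v <- prod(bx[2, ] - bx[1, ] + 1)
        if (v > bestvol) { bestvol <- v; best <- p }
      }
      if (is.null(best))
        stop(sprintf("stitching error: tile %d overlaps no earlier tile", t))
      bx <- overlap_box(off, best, t)
      sub <- function(k) {
        l <- bx[1, ] - off[[k]]; h <- bx[2, ] - off[[k]]
        tiles[[k]]$channels[[rch]][l[1]:h[1], l[2]:h[2], l[3]:h[3], drop = FALSE]
      }
      a <- sub(best); b <- sub(t)
      s <- cpp_best_shift(a, b, dim(a), as.integer(search_radius), 27L)
      if (s[4] > -1) {
        tiles[[t]]$origin_um <- tiles[[t]]$origin_um + s[1:3] * vs
        off <- offs()
      }
    }
  }
  off <- offs()
  gdim <- as.integer(apply(do.call(rbind, Map(function(o, d) o + d, off, dims)), 2, max))
  o0 <- apply(do.call(rbind, lapply(tiles, `[[`, "origin_um")), 2, min)
  # pyramid depth from the narrowest pairwise overlap
  if (is.null(pyramid_levels)) {
    mo <- Inf
    for (i in seq_along(tiles)) for (j in seq_along(tiles)) if (i < j) {
      bx <- overlap_box(off, i, j)
      if (!is.null(bx)) mo <- min(mo, min(bx[2, ] - bx[1, ] + 1))
    }
    pyramid_levels <- if (is.finite(mo)) max(1L, as.integer(floor(log2(max(2, mo))) - 1L)) else 1L
  }
  pyramid_levels <- min(pyramid_levels, max_levels(gdim), 4L)
  place <- function(a, o, fill = NA_real_) {
    g <- array(fill, gdim)
    d <- dim(a)
    g[o[1] + 1:d[1], o[2] + 1:d[2], o[3] + 1:d[3]] <- a
    g
  }
  weights <- vector("list", length(tiles))
  for (t in seq_along(tiles)) {
    valid <- !is.na(tiles[[t]]$channels[[1]])
    weights[[t]] <- place(feather_weight(valid), off[[t]], fill = 0)
  }
  wpyr <- lapply(weights, pyr_gauss, levels = pyramid_levels)
  out_ch <- list()
  den1 <- Reduce(`+`, weights)
  for (ch in chn) {
    num <- NULL; den <- NULL
    for (t in seq_along(tiles)) {
      g <- place(tiles[[t]]$channels[[ch]], off[[t]])
      g <- cpp_fill_nearest(g, gdim)
      dim(g) <- gdim
      lap <- pyr_laplace(pyr_gauss(g, pyramid_levels))
      if (is.null(num)) {
        num <- lapply(seq_len(pyramid_levels), function(l) lap[[l]] * wpyr[[t]][[l]])
        den <- lapply(wpyr[[t]], identity)
      } else {
        for (l in seq_len(pyramid_levels)) {
          num[[l]] <- num[[l]] + lap[[l]] * wpyr[[t]][[l]]
          den[[l]] <- den[[l]] + wpyr[[t]][[l]]
        }
      }
    }
    comb <- lapply(seq_len(pyramid_levels), function(l) {
      r <- num[[l]] / pmax(den[[l]], 1e-12)
      r[den[[l]] <= 0] <- 0
      r
    })
    res <- pmax(pyr_collapse(comb), 0)  # band-pass ringing can undershoot zero
    res[den1 <= 0] <- NA_real_
    out_ch[[ch]] <- res
  }
  volume_image(out_ch, voxel_size_um = vs, origin_um = o0,
               timepoint_h = tiles[[1]]$timepoint_h)
}

#' Full reconstruction chain: flat-field, shear correction, stitch, deconvolve
#'
#' @param tiles List of [tile_stack()] objects of one time point (all
#'   channels, all tiles).
#' @param flatfield Estimate and apply a per-channel flat-field model from
#'   the tile frames.
#' @param optics An [optics_model()]; when given, every channel is
#'   Richardson-Lucy deconvolved with the corresponding light-sheet PSF.
#' @param iterations RL iterations.
#' @param search_radius Stitching registration radius (voxels).
#' @param crop_to Optional reference [volume_image()]; the result is cropped
#'   to its grid.
#' @param fill_na Replace out-of-data voxels by 0 in the returned volume
#'   (a validity mask is kept in attribute `"valid"`).
#' @return A multi-channel [volume_image()].
#' @export
reconstruct_volume <- function(tiles, flatfield = TRUE, optics = NULL,
                               iterations = 10L, search_radius = 5L,
                               crop_to = NULL, fill_na = TRUE) {
  chn <- unique(vapply(tiles, `[[`, "", "channel"))
  by_tile <- split(tiles, vapply(tiles, function(t) paste(t$tile_index, collapse = ","), ""))
  ff <- list()
  if (isTRUE(flatfield)) {
    # soil texture carries the vignetting signature; the weight matrix from
    # the particle channel is shared by all channels of the same camera
    if ("particle" %in% chn) {
      shared <- estimate_flatfield(Filter(function(t) t$channel == "particle", tiles))
      for (ch in chn) ff[[ch]] <- shared
    } else {
      for (ch in chn)
        ff[[ch]] <- estimate_flatfield(Filter(function(t) t$channel == ch, tiles))
    }
  }
  vols <- lapply(by_tile, function(tl) {
    parts <- lapply(tl, function(t) {
      if (!is.null(ff[[t$channel]])) t <- apply_flatfield(t, ff[[t$channel]])
      shear_correct(t)
    })
    ch <- lapply(parts, function(v) v$channels[[1]])
    names(ch) <- vapply(tl, `[[`, "", "channel")
    volume_image(ch[chn], voxel_size_um = parts[[1]]$voxel_size_um,
                 origin_um = parts[[1]]$origin_um, timepoint_h = parts[[1]]$timepoint_h)
  })
  out <- stitch_tiles(unname(vols), search_radius = search_radius)
  if (!is.null(crop_to)) {
    lo <- as.integer(round((crop_to$origin_um - out$origin_um) / out$voxel_size_um))
    d <- vol_dim(crop_to)
    gd <- vol_dim(out)
    # window clipped to the stitched grid, padded with NA where it falls short
    out$channels <- lapply(out$channels, function(a) {
      g <- array(NA_real_, d)
      src_lo <- pmax(lo + 1L, 1L); src_hi <- pmin(lo + d, gd)
      if (all(src_hi >= src_lo)) {
        dst_lo <- src_lo - lo; dst_hi <- src_hi - lo
        g[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
          a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
      }
      g
    })
    out$origin_um <- crop_to$origin_um
  }
  valid <- !is.na(out$channels[[1]])
  if (fill_na) out <- map_channels(out, function(a) { a[is.na(a)] <- 0; a })
  if (!is.null(optics)) {
    psf <- make_lightsheet_psf(optics, out$voxel_size_um)
    out <- lr_deconvolve(out, psf, iterations = iterations)
  }
  attr(out, "valid") <- valid
  out
}
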