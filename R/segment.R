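#' Segment the root by seeded region growing on the scattering channel
#'
#' Flood fill of voxels at or above the threshold connected to the seeds;
#' the largest seed-connected component is kept and closed morphologically
#' (radius 1) to bridge 1-voxel gaps in the scattering signal.
#'
#' @param scatter A [volume_image()] (channel `scatter` if present) or array.
#' @param seeds Integer matrix (n x 3) of 1-based voxel indices (z, y, x).
#' @param threshold Intensity threshold; every seed must be at or above it.
#' @param connectivity 6 or 26 (default 26).
#' @param closing_radius Radius (voxels) of the morphological closing.
#' @return Logical root mask with attributes `seeds` and `threshold`.
#' @export
segment_root <- function(scatter, seeds, threshold, connectivity = 26L,
                         closing_radius = 1L) {
  a <- if (inherits(scatter, "volume_image")) {
    if ("scatter" %in% names(scatter$channels)) vol_channel(scatter, "scatter")
    else vol_channel(scatter)
  } else scatter
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(a)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (any(s < 1) || any(s > d)) stop("seed outside volume: ", paste(s, collapse = ","))
    if (a[s[1], s[2], s[3]] < threshold)
      stop(sprintf("seed error: voxel (%d,%d,%d) intensity %.3g below threshold %.3g",
                   s[1], s[2], s[3], a[s[1], s[2], s[3]], threshold))
  }
  grown <- cpp_region_grow(a, d, seeds - 1L, threshold, as.integer(connectivity))
  dim(grown) <- d
  lab <- cpp_label(grown, d, as.integer(connectivity))
  if (max(lab) > 1) {
    keep <- which.max(tabulate(lab[lab > 0]))
    grown <- lab == keep
  }
  if (closing_radius > 0) {
    grown <- cpp_morph(grown, d, as.integer(closing_radius), TRUE)
    grown <- cpp_morph(grown, d, as.integer(closing_radius), FALSE)
    dim(grown) <- d
  }
  attr(grown, "seeds") <- seeds
  attr(grown, "threshold") <- threshold
  grown
}

#' Default root seed: the brightest scattering voxel
#' @param scatter A [volume_image()] or array.
#' @return 1 x 3 integer matrix (z, y, x).
#' @export
default_root_seed <- function(scatter) {
  a <- if (inherits(scatter, "volume_image")) vol_channel(scatter, "scatter") else scatter
  matrix(arrayInd(which.max(a), dim(a)), 1)
}

#' Segment the pore space from the particle and GFP channels
#'
#' Sulforhodamine B stains particles only superficially, so the particle
#' channel alone under-segments particle interiors; the inverted GFP signal
#' (bacteria live in the pore liquid) is averaged in to reinforce it.
#' Channels are min-max normalized, averaged with equal weight (degenerate
#' constant channels are dropped from the average), thresholded, and closed
#' (dilation then erosion). Pores are everything that is neither particle nor
#' root.
#'
#' @param particle_ch A [volume_image()] channel or array (particle signal).
#' @param gfp_ch Optional GFP channel on the same grid.
#' @param root Optional logical root mask, excluded from the pore space.
#' @param threshold Threshold on the normalized composite in \[0, 1\];
#'   `NULL` uses Otsu initialization.
#' @param morph_radius Closing radius (voxels).
#' @return Logical pore mask (TRUE = pore / liquid space).
#' @export
segment_pores <- function(particle_ch, gfp_ch = NULL, root = NULL,
                          threshold = NULL, morph_radius = 1L) {
  p <- if (inherits(particle_ch, "volume_image")) {
    if ("particle" %in% names(particle_ch$channels)) vol_channel(particle_ch, "particle")
    else vol_channel(particle_ch)
  } else particle_ch
  g <- if (inherits(gfp_ch, "volume_image")) {
    if ("gfp" %in% names(gfp_ch$channels)) vol_channel(gfp_ch, "gfp") else vol_channel(gfp_ch)
  } else gfp_ch
  d <- dim(p)
  parts <- list()
  if (diff(range(p, na.rm = TRUE)) > 0) parts <- c(parts, list(norm01(p)))
  if (!is.null(g)) {
    if (!identical(dim(g), d)) stop("channel grids differ")
    if (diff(range(g, na.rm = TRUE)) > 0) parts <- c(parts, list(1 - norm01(g)))
  }
  if (!length(parts)) {
    particles <- array(FALSE, d)
  } else {
    comp <- Reduce(`+`, parts) / length(parts)
    thr <- threshold %||% otsu_threshold(comp)
    if (thr < 0 || thr > 1)
      stop("parameter error: threshold must lie in [0, 1] on the normalized composite")
    particles <- comp >= thr
    if (morph_radius > 0) {
      particles <- cpp_morph(particles, d, as.integer(morph_radius), TRUE)
      particles <- cpp_morph(particles, d, as.integer(morph_radius), FALSE)
      dim(particles) <- d
    }
  }
  pores <- !particles
  if (!is.null(root)) {
    if (!identical(dim(root), d)) stop("channel grids differ")
    pores <- pores & !root
  }
  pores
}

#' Local thickness pore-size map
#'
#' For every pore voxel, the diameter (um) of the largest sphere fully
#' contained in the pore space (grid border counts as solid) that contains
#' the voxel; 0 on non-pore voxels. Implemented via the exact Euclidean
#' distance transform with redundant-sphere pruning and sphere painting, and
#' identical to an exhaustive all-centres search.
#'
#' @param pores Logical pore mask.
#' @param voxel_size_um Voxel size, scalar or (z, y, x).
#' @return Numeric array of pore diameters (um).
#' @export
local_thickness <- function(pores, voxel_size_um) {
  d <- dim(pores)
  if (!any(pores)) {
    warning("empty pore mask")
    return(array(0, d))
  }
  out <- cpp_local_thickness(pores, d, rep_len(as.numeric(voxel_size_um), 3))
  dim(out) <- d
  out
}
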