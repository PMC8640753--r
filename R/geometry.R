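#' Mesocosm chamber geometry
#'
#' The growth chamber is a sealed cuboid assembled from glass slides and PDMS
#' spacers. The default dimensions, 22 x 65 x 3 mm, hold 4,290 mm^3 of
#' transparent soil, water, nutrients and atmosphere.
#'
#' Axis convention throughout the package: arrays are indexed (z, y, x) where
#' z is the chamber depth (optical/detection axis), y the height (root growth
#' axis) and x the width.
#'
#' @param width_mm,height_mm,depth_mm Chamber dimensions in mm.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(width_mm = 22, height_mm = 65, depth_mm = 3) {
  stopifnot(width_mm > 0, height_mm > 0, depth_mm > 0)
  structure(list(width_mm = width_mm, height_mm = height_mm, depth_mm = depth_mm),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> %g x %g x %g mm (%g mm^3)\n",
              x$width_mm, x$height_mm, x$depth_mm, chamber_volume(x)))
  invisible(x)
}

#' Chamber volume in mm^3
#' @param chamber A [chamber_geometry()].
#' @return Volume in mm^3.
#' @export
chamber_volume <- function(chamber) {
  chamber$width_mm * chamber$height_mm * chamber$depth_mm
}

# chamber extents in um, axis order (z, y, x)
chamber_extent_um <- function(chamber) {
  1000 * c(chamber$depth_mm, chamber$height_mm, chamber$width_mm)
}

#' Scan geometry of the light-sheet acquisition
#'
#' Describes how the mesocosm is swept through the light sheet: the sample is
#' translated along an axis at `scan_angle_deg` (nominally 45 degrees) to the
#' illumination and detection axes, acquiring `slices_per_tile` camera frames
#' per pass in steps of `slice_step_um`, with a grid of overlapping passes.
#'
#' @param scan_angle_deg Angle between scan axis and detection axis (degrees).
#' @param slice_step_um Stage step between successive frames (um along the
#'   scan axis). `NULL` lets the renderer pick a voxel-aligned step.
#' @param slices_per_tile Number of frames per scan pass (`NULL` = enough to
#'   cover the volume depth).
#' @param tile_grid Integer pair: number of tiles along (y, x).
#' @param tile_overlap_fraction Fractional overlap between adjacent tiles, in
#'   \[0, 1).
#' @param vertical_step_mm Stage step between vertical scan positions (mm);
#'   instrument bookkeeping, 4 mm in the reference configuration.
#' @param footprint_mm Scan footprint (y, x) in mm used for imaged-volume
#'   arithmetic.
#' @param chamber A [chamber_geometry()].
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(scan_angle_deg = 45, slice_step_um = NULL,
                          slices_per_tile = NULL, tile_grid = c(1L, 1L),
                          tile_overlap_fraction = 0.2, vertical_step_mm = 4,
                          footprint_mm = c(60, 20), chamber = chamber_geometry()) {
  if (!is.finite(scan_angle_deg)) stop("scan metadata error: missing or invalid scan angle")
  if (tile_overlap_fraction < 0 || tile_overlap_fraction >= 1)
    stop("tile_overlap_fraction must be in [0, 1)")
  stopifnot(length(tile_grid) == 2, all(tile_grid >= 1))
  structure(list(scan_angle_deg = scan_angle_deg, slice_step_um = slice_step_um,
                 slices_per_tile = slices_per_tile, tile_grid = as.integer(tile_grid),
                 tile_overlap_fraction = tile_overlap_fraction,
                 vertical_step_mm = vertical_step_mm, footprint_mm = footprint_mm,
                 chamber = chamber),
            class = "scan_geometry")
}

#' Imaged sample volume in mm^3
#'
#' The scan footprint clipped to the chamber depth: a 60 x 20 mm footprint
#' over a 3 mm-thick chamber images 3,600 mm^3.
#'
#' @param scan A [scan_geometry()].
#' @return Volume in mm^3.
#' @export
imaged_volume <- function(scan) {
  prod(scan$footprint_mm) * scan$chamber$depth_mm
}

#' Light-sheet optics parameters
#'
#' @param sheet_fwhm_um Light-sheet thickness (FWHM, um); 50 um in the
#'   reference instrument (theoretical limit 47 um).
#' @param lateral_fwhm_um Effective in-plane resolution (FWHM, um) at the
#'   working voxel scale.
#' @param wavelength_nm Illumination wavelength.
#' @param sheet_height_mm Sheet height (mm).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(sheet_fwhm_um = 50, lateral_fwhm_um = 50,
                         wavelength_nm = 488, sheet_height_mm = 5) {
  stopifnot(sheet_fwhm_um > 0, lateral_fwhm_um > 0)
  structure(list(sheet_fwhm_um = sheet_fwhm_um, lateral_fwhm_um = lateral_fwhm_um,
                 wavelength_nm = wavelength_nm, sheet_height_mm = sheet_height_mm),
            class = "optics_model")
}

#' Detection noise and vignetting model for the forward renderer
#'
#' @param photon_gain Counts per CFU-equivalent of signal.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param background_offset Detector offset (counts).
#' @param vignetting_min Multiplicative vignetting value at the frame corners,
#'   in (0, 1]; 1 disables vignetting. The field is a separable quadratic
#'   fall-off, smooth and equal to 1 at the frame centre.
#' @param rng_seed Integer seed; a fixed seed renders bit-identical tiles.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_gain = 1, read_noise_sd = 0,
                        background_offset = 0, vignetting_min = 1, rng_seed = 1L) {
  stopifnot(vignetting_min > 0, vignetting_min <= 1, read_noise_sd >= 0)
  structure(list(photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 background_offset = background_offset,
                 vignetting_min = vignetting_min, rng_seed = as.integer(rng_seed)),
            class = "noise_model")
}

#' Vignetting field for a frame of given size
#'
#' Separable quadratic fall-off; per-axis minimum is `sqrt(vignetting_min)` at
#' the frame edge so corners reach `vignetting_min`.
#'
#' @param noise A [noise_model()].
#' @param nrow,ncol Frame dimensions.
#' @return Matrix of multiplicative factors in (0, 1].
#' @export
vignetting_field <- function(noise, nrow, ncol) {
  m <- noise$vignetting_min
  if (m >= 1) return(matrix(1, nrow, ncol))
  cmin <- sqrt(m)
  axis_profile <- function(n) {
    if (n == 1) return(1)
    t <- (2 * seq_len(n) - n - 1) / (n - 1)  # -1..1
    1 - (1 - cmin) * t^2
  }
  outer(axis_profile(nrow), axis_profile(ncol))
}
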