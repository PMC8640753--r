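#' Multi-channel axis-aligned volume image
#'
#' Container for reconstructed (or ground-truth) voxel data. Channels share a
#' common grid; voxel `[i, j, k]` (1-based) is centred at
#' `origin_um + (c(i, j, k) - 1) * voxel_size_um`, axis order (z, y, x).
#'
#' @param channels Named list of 3-D numeric arrays (conventional names:
#'   `scatter`, `particle`, `gfp`), or a single array (named `"value"`).
#' @param voxel_size_um Voxel size, scalar or length-3 (z, y, x), in um.
#' @param origin_um Physical position of voxel (1,1,1), um.
#' @param timepoint_h Hours post inoculation (NA if not a time-series member).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(channels, voxel_size_um, origin_um = c(0, 0, 0),
                         timepoint_h = NA_real_) {
  if (is.array(channels)) channels <- list(value = channels)
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be named")
  d <- dim(channels[[1]])
  stopifnot(length(d) == 3)
  for (ch in channels) if (!identical(dim(ch), d)) stop("channels must share one grid")
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3)
  if (any(voxel_size_um <= 0)) stop("voxel size must be positive")
  structure(list(channels = channels, voxel_size_um = voxel_size_um,
                 origin_um = as.numeric(origin_um), timepoint_h = timepoint_h),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- vol_dim(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels (z,y,x), voxel %s um, channels: %s\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size_um, 4), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  if (is.finite(x$timepoint_h)) cat(sprintf("  t = %g h post inoculation\n", x$timepoint_h))
  invisible(x)
}

#' Dimensions of a volume image (z, y, x)
#' @param vol A `volume_image`.
#' @export
vol_dim <- function(vol) dim(vol$channels[[1]])

#' Extract one channel array from a volume image
#' @param vol A `volume_image` (a bare array passes through).
#' @param name Channel name; defaults to the first channel.
#' @return 3-D numeric array.
#' @export
vol_channel <- function(vol, name = NULL) {
  if (is.array(vol)) return(vol)
  stopifnot(inherits(vol, "volume_image"))
  if (is.null(name)) return(vol$channels[[1]])
  if (!name %in% names(vol$channels)) stop("no channel called ", name)
  vol$channels[[name]]
}

# apply a function to every channel, keeping metadata
map_channels <- function(vol, f, ...) {
  vol$channels <- lapply(vol$channels, f, ...)
  vol
}

#' Crop a volume image to a voxel index window
#' @param vol A `volume_image`.
#' @param zlim,ylim,xlim 1-based inclusive index ranges (NULL = full extent).
#' @export
crop_volume <- function(vol, zlim = NULL, ylim = NULL, xlim = NULL) {
  d <- vol_dim(vol)
  zlim <- zlim %||% c(1L, d[1]); ylim <- ylim %||% c(1L, d[2]); xlim <- xlim %||% c(1L, d[3])
  vol$channels <- lapply(vol$channels, function(a)
    a[zlim[1]:zlim[2], ylim[1]:ylim[2], xlim[1]:xlim[2], drop = FALSE])
  vol$origin_um <- vol$origin_um + (c(zlim[1], ylim[1], xlim[1]) - 1) * vol$voxel_size_um
  vol
}

#' Raw sheared camera frames of one scan pass
#'
#' Frames are indexed (slice, row, col); slice k of a pass translated at angle
#' theta to the detection axis sees the sample displaced by
#' `k * slice_step_um * sin(theta)` along the frame rows.
#'
#' @param frames 3-D array (slice, row, col) of non-negative intensities.
#' @param channel One of `"scatter"`, `"particle"`, `"gfp"`.
#' @param tile_index Integer pair (i, j) of the tile in the scan grid.
#' @param origin_um Sample position (z, y, x in um) of frame pixel (1,1) of
#'   slice 1.
#' @param scan_angle_deg,slice_step_um,pixel_size_um Scan metadata.
#' @param timepoint_h Hours post inoculation.
#' @return An object of class `tile_stack`.
#' @export
tile_stack <- function(frames, channel, tile_index, origin_um,
                       scan_angle_deg, slice_step_um, pixel_size_um,
                       timepoint_h = NA_real_) {
  stopifnot(length(dim(frames)) == 3, min(frames, na.rm = TRUE) >= 0)
  channel <- match.arg(channel, c("scatter", "particle", "gfp", "value"))
  structure(list(frames = frames, channel = channel,
                 tile_index = as.integer(tile_index), origin_um = as.numeric(origin_um),
                 scan_angle_deg = scan_angle_deg, slice_step_um = slice_step_um,
                 pixel_size_um = pixel_size_um, timepoint_h = timepoint_h),
            class = "tile_stack")
}

#' @export
print.tile_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<tile_stack> tile (%d,%d) channel %s: %d slices of %d x %d px, step %g um at %g deg\n",
              x$tile_index[1], x$tile_index[2], x$channel, d[1], d[2], d[3],
              x$slice_step_um, x$scan_angle_deg))
  invisible(x)
}
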