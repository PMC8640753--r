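# Tile windows along one axis: n windows of width covering [lo, hi] with the
# requested fractional overlap.
tile_windows <- function(lo, hi, n, overlap) {
  span <- hi - lo + 1
  if (n == 1) return(list(starts = lo, width = span))
  w <- ceiling(span / (n - (n - 1) * overlap))
  starts <- lo + round(seq(0, span - w, length.out = n))
  list(starts = starts, width = w)
}

#' Render a truth volume through the light-sheet forward model
#'
#' Samples the (PSF-blurred) truth on planes sheared at the scan angle — the
#' sample is translated along an axis at `scan_angle_deg` to the detection
#' axis, so slice k of a pass sees the sample displaced by
#' `k * slice_step_um * sin(theta)` along the frame rows — then applies
#' vignetting, gain, offset and Gaussian read noise per frame. Adjacent tiles
#' share the configured overlap fraction; rendering is deterministic given
#' the seed.
#'
#' By default the slice step is `voxel / cos(theta)` so successive slices land
#' exactly one truth voxel deeper and (at 45 degrees) the per-slice shear is
#' exactly one voxel, making the shear exactly invertible.
#'
#' @param truth A [volume_image()] with isotropic voxels (the truth raster).
#' @param scan A [scan_geometry()].
#' @param optics An [optics_model()] for the PSF blur, or `NULL` for an ideal
#'   (delta) PSF.
#' @param noise A [noise_model()]; defaults disable noise and vignetting.
#' @param seed Seed override (defaults to `noise$rng_seed`).
#' @return List of [tile_stack()] objects (tiles x channels).
#' @export
render_scan <- function(truth, scan, optics = NULL, noise = noise_model(),
                        seed = NULL) {
  stopifnot(inherits(truth, "volume_image"))
  vs <- truth$voxel_size_um
  if (max(abs(vs - vs[1])) > 1e-9) stop("render_scan requires isotropic truth voxels")
  h <- vs[1]
  d <- vol_dim(truth)
  th <- scan$scan_angle_deg * pi / 180
  if (cos(th) <= 1e-6) stop("scan angle must be < 90 degrees")
  step <- scan$slice_step_um %||% (h / cos(th))
  if (step < h - 1e-9) stop("truth voxel size must not exceed the slice step")
  dz_vox <- step * cos(th) / h
  shear_vox <- step * sin(th) / h
  K <- scan$slices_per_tile %||% (as.integer(ceiling((d[1] - 1) / dz_vox)) + 1L)
  if ((K - 1) * dz_vox < d[1] - 1 - 1e-9)
    stop(sprintf("coverage error: slices cover z up to voxel %.1f of %d",
                 (K - 1) * dz_vox + 1, d[1]))
  # shear makes early rows of deep slices look upstream of the tile window
  span_lo <- -as.integer(ceiling((K - 1) * shear_vox))
  wy <- tile_windows(span_lo, d[2] - 1L, scan$tile_grid[1], scan$tile_overlap_fraction)
  wx <- tile_windows(0L, d[3] - 1L, scan$tile_grid[2], scan$tile_overlap_fraction)
  blurred <- truth$channels
  if (!is.null(optics)) {
    psf <- make_lightsheet_psf(optics, h)
    blurred <- lapply(blurred, function(a) conv_sep3(a, psf$sep$kz, psf$sep$ky, psf$sep$kx))
  }
  vig <- vignetting_field(noise, wy$width, wx$width)
  tkey <- if (is.finite(truth$timepoint_h)) round(truth$timepoint_h * 100) else 0
  tiles <- list()
  with_seed(derive_seed(seed %||% noise$rng_seed, tkey), {
    for (i in seq_along(wy$starts)) for (j in seq_along(wx$starts)) {
      for (ch in names(blurred)) {
        raw <- cpp_sample_sheared(blurred[[ch]], d, K, wy$width, wx$width,
                                  0, wy$starts[i], wx$starts[j], dz_vox, shear_vox)
        dim(raw) <- c(K, wy$width, wx$width)
        raw <- raw * noise$photon_gain *
          aperm(array(vig, c(wy$width, wx$width, K)), c(3, 1, 2))
        raw <- raw + noise$background_offset
        if (noise$read_noise_sd > 0)
          raw <- raw + array(stats::rnorm(length(raw), 0, noise$read_noise_sd), dim(raw))
        tiles[[length(tiles) + 1L]] <- tile_stack(
          frames = pmax(raw, 0), channel = ch, tile_index = c(i, j),
          origin_um = truth$origin_um + c(0, wy$starts[i] * h, wx$starts[j] * h),
          scan_angle_deg = scan$scan_angle_deg, slice_step_um = step,
          pixel_size_um = h, timepoint_h = truth$timepoint_h)
      }
    }
  })
  tiles
}

#' Synthetic mesocosm phantom: packing, growing root and bacterial field
#'
#' Assembles the full ground-truth scene used to exercise every downstream
#' stage: a seeded particle packing, a root elongating over hourly time
#' points, the static pore-size map (local thickness of the pore space), and
#' a pulsatile bacterial density field with near-root accumulation and
#' small-pore bias. [phantom_truth()] rasterizes one time point into a
#' 3-channel truth volume via the fluorescence calibration forward model.
#'
#' @param chamber A [chamber_geometry()] (defaults to the 22 x 65 x 3 mm
#'   study chamber; tests use reduced chambers as their stated problem size).
#' @param voxel_size_um Truth raster voxel size (um).
#' @param target_porosity,size_range_um Particle packing parameters.
#' @param root List of [grow_root()] arguments (base, direction, radius,
#'   elongation rate, initial length).
#' @param bacteria A [bacteria_field_spec()].
#' @param calibration List with `intensity_per_od` (a), `intensity_offset`
#'   (b) and `cfu_per_od` (c): GFP pixel intensity is `a * density / c + b`.
#' @param intensities Scatter/particle channel intensities (counts).
#' @param times_h Imaging time points, hours post inoculation.
#' @param seed Master seed.
#' @return An object of class `phantom_mesocosm`.
#' @export
phantom_mesocosm <- function(chamber = chamber_geometry(), voxel_size_um = 50,
                             target_porosity = 0.6, size_range_um = c(250, 1250),
                             root = list(), bacteria = bacteria_field_spec(),
                             calibration = list(intensity_per_od = 1000,
                                                intensity_offset = 50,
                                                cfu_per_od = 2e8),
                             intensities = list(scatter = 1000, particle = 600),
                             times_h = 20:42, seed = 1L) {
  ext <- chamber_extent_um(chamber)
  dims <- pmax(1L, as.integer(round(ext / voxel_size_um)))
  packing <- make_particle_packing(chamber, size_range_um, target_porosity,
                                   seed = derive_seed(seed, 10L))
  particle_mask <- rasterize_packing(packing, voxel_size_um, dims)
  pore_size <- local_thickness(!particle_mask, voxel_size_um)
  root_args <- utils::modifyList(
    list(base_um = c(ext[1] / 2, 500, ext[3] / 2), direction = c(0, 1, 0),
         radius_um = 250, elongation_rate_um_h = 100, initial_length_um = 2000),
    root)
  hotspots <- if (bacteria$n_hotspots > 0 && bacteria$hotspot_density > 0)
    hotspot_positions(bacteria, pore_size, voxel_size_um, derive_seed(seed, 20L))
  else matrix(numeric(0), 0, 3)
  structure(list(chamber = chamber, voxel_size_um = voxel_size_um, dims = dims,
                 packing = packing, particle_mask = particle_mask,
                 pore_size_um = pore_size, root_args = root_args,
                 bacteria = bacteria, hotspots = hotspots,
                 calibration = calibration, intensities = intensities,
                 times_h = times_h, seed = seed),
            class = "phantom_mesocosm")
}

#' @export
print.phantom_mesocosm <- function(x, ...) {
  cat(sprintf("<phantom_mesocosm> %d x %d x %d voxels at %g um, %d particles, %d time points\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_um,
              length(x$packing$radii_um), length(x$times_h)))
  invisible(x)
}

#' Ground truth of one phantom time point
#'
#' @param ph A [phantom_mesocosm()].
#' @param timepoint_h Hours post inoculation.
#' @return List with `volume` (3-channel truth [volume_image()]), `root`
#'   (the [grow_root()] model), `root_mask`, `density` (CFU/mL array) and
#'   `soil_mask` (pore voxels outside root and particles).
#' @export
phantom_truth <- function(ph, timepoint_h) {
  ra <- ph$root_args
  root <- grow_root(base_um = ra$base_um, direction = ra$direction,
                    radius_um = ra$radius_um,
                    elongation_rate_um_h = ra$elongation_rate_um_h,
                    timepoint_h = timepoint_h,
                    initial_length_um = ra$initial_length_um, chamber = ph$chamber)
  root_mask <- rasterize_root(root, ph$voxel_size_um, ph$dims)
  density <- bacteria_density_field(ph$bacteria, root_mask, ph$pore_size_um,
                                    ph$voxel_size_um, timepoint_h,
                                    seed = ph$seed, hotspots = ph$hotspots)
  cal <- ph$calibration
  gfp <- cal$intensity_per_od * density / cal$cfu_per_od + cal$intensity_offset
  vol <- volume_image(
    list(scatter = ph$intensities$scatter * root_mask,
         particle = ph$intensities$particle * ph$particle_mask,
         gfp = gfp),
    voxel_size_um = ph$voxel_size_um, timepoint_h = timepoint_h)
  list(volume = vol, root = root, root_mask = root_mask, density = density,
       soil_mask = !ph$particle_mask & !root_mask)
}
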