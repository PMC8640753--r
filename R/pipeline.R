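#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage (chamber, phantom, scan, optics,
#' noise, reconstruction, segmentation, calibration, quantification), a
#' single RNG seed and an output directory. The configuration round-trips
#' losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param ... Named overrides merged into the defaults (nested lists merge
#'   recursively).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    output_dir = "rhizolight_out",
    chamber = list(width_mm = 22, height_mm = 65, depth_mm = 3),
    phantom = list(
      enabled = TRUE, voxel_size_um = 50, target_porosity = 0.6,
      size_range_um = c(250, 1250), times_h = 20:42,
      root = list(radius_um = 250, elongation_rate_um_h = 100,
                  initial_length_um = 2000),
      bacteria = list(),
      calibration = list(intensity_per_od = 1000, intensity_offset = 50,
                         cfu_per_od = 2e8),
      intensities = list(scatter = 1000, particle = 600)),
    scan = list(scan_angle_deg = 45, tile_grid = c(1L, 1L),
                tile_overlap_fraction = 0.2),
    optics = list(sheet_fwhm_um = 50, lateral_fwhm_um = 50),
    noise = list(photon_gain = 1, read_noise_sd = 0, background_offset = 0,
                 vignetting_min = 1),
    reconstruction = list(iterations = 10L, flatfield = TRUE, search_radius = 5L),
    segmentation = list(root_threshold_frac = 0.5, pore_threshold = NULL,
                        morph_radius = 1L),
    calibration = list(n_standards = 12L, od_range = c(1.2e-3, 3.0),
                       noise_frac = 0.01),
    quantification = list(cutoff_um = 200, tip_base_cutoff_um = 2000,
                          analysis_radius_um = 1500, kinematics_bin_um = 500,
                          discard_first = 5L))
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path File path.
#' @param config A [pipeline_config()].
#' @rdname config_io
#' @export
read_config <- function(path) {
  cfg <- pipeline_config()
  cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulated suspension calibration dataset
#'
#' Emulates the suspension calibration protocol: a geometric dilution series
#' of `n` OD600 points across `od_range`, imaged intensities
#' `a * OD + b` and plate counts `c * OD`, each with multiplicative Gaussian
#' noise of relative magnitude `noise_frac`.
#'
#' @param truth List with `intensity_per_od`, `intensity_offset`,
#'   `cfu_per_od`.
#' @param n Number of dilution points.
#' @param od_range OD600 range (min, max).
#' @param noise_frac Relative measurement noise.
#' @param seed Integer seed.
#' @return List of data frames `standards` and `cfu_points`.
#' @export
simulate_calibration <- function(truth, n = 12L, od_range = c(1.2e-3, 3.0),
                                 noise_frac = 0.01, seed = 1L) {
  od <- exp(seq(log(od_range[1]), log(od_range[2]), length.out = n))
  with_seed(seed, {
    intensity <- (truth$intensity_per_od * od + truth$intensity_offset) *
      (1 + stats::rnorm(n, 0, noise_frac))
    cfu <- truth$cfu_per_od * od * (1 + stats::rnorm(n, 0, noise_frac))
  })
  list(standards = data.frame(intensity = intensity, od600 = od),
       cfu_points = data.frame(od600 = od, cfu = cfu))
}

#' Analyze a phantom time series end to end
#'
#' For every time point: render the truth through the forward model,
#' reconstruct (flat-field, shear correction, stitching, deconvolution),
#' segment the root and the pore space, convert GFP intensity to cell
#' density via a fitted calibration, and classify voxels. Returns indicator
#' tables for all grouping schemes, the kinematics diagram and the
#' rhizosphere/bulk time-series summary.
#'
#' @param ph A [phantom_mesocosm()].
#' @param config A [pipeline_config()].
#' @return List with `indicators` (data frame over schemes), `kinematics`,
#'   `summary`, `calibration`, and per-time `root_volumes_mm3`.
#' @export
analyze_phantom_series <- function(ph, config = pipeline_config()) {
  scn <- scan_geometry(scan_angle_deg = config$scan$scan_angle_deg,
                       tile_grid = config$scan$tile_grid,
                       tile_overlap_fraction = config$scan$tile_overlap_fraction,
                       chamber = ph$chamber)
  opt <- do.call(optics_model, config$optics)
  noi <- do.call(noise_model, c(config$noise, list(rng_seed = derive_seed(ph$seed, 30L))))
  calt <- ph$calibration
  cal_data <- simulate_calibration(calt, n = config$calibration$n_standards,
                                   od_range = config$calibration$od_range,
                                   noise_frac = config$calibration$noise_frac,
                                   seed = derive_seed(ph$seed, 40L))
  calib <- fit_calibration(cal_data$standards, cal_data$cfu_points)
  times <- ph$times_h
  vs <- ph$voxel_size_um
  qc <- config$quantification
  dens_l <- list(); rootd_l <- list(); fromtip_l <- list(); soil_l <- list()
  groups <- list(rhizosphere_bulk = list(), by_pore_size = list(),
                 tip_base = list(), by_root_distance = list(),
                 by_tip_distance = list())
  root_vol <- numeric(length(times))
  pore_mask <- NULL; pore_size <- NULL
  max_tip <- 0
  for (ti in seq_along(times)) {
    t <- times[ti]
    tr <- phantom_truth(ph, t)
    tiles <- render_scan(tr$volume, scn, optics = opt, noise = noi)
    rec <- reconstruct_volume(tiles, flatfield = config$reconstruction$flatfield,
                              optics = opt,
                              iterations = config$reconstruction$iterations,
                              search_radius = config$reconstruction$search_radius,
                              crop_to = tr$volume)
    sc_ch <- vol_channel(rec, "scatter")
    thr <- config$segmentation$root_threshold_frac * max(sc_ch)
    root <- segment_root(sc_ch, default_root_seed(sc_ch), thr)
    root_vol[ti] <- sum(root) * prod(rep_len(vs, 3)) / 1e9
    if (is.null(pore_mask)) {
      # particles are static; pore geometry is segmented once
      pore_mask <- segment_pores(vol_channel(rec, "particle"),
                                 vol_channel(rec, "gfp"), root = NULL,
                                 threshold = config$segmentation$pore_threshold,
                                 morph_radius = config$segmentation$morph_radius)
      pore_size <- local_thickness(pore_mask, vs)
    }
    soil <- pore_mask & !root
    dens <- intensity_to_density(vol_channel(rec, "gfp"), calib)
    dens[!soil] <- 0
    rd <- distance_from_root(root, vs)
    cl <- centerline_and_tip(root, vs)
    max_tip <- max(max_tip, max(cl$from_tip_um[soil]))
    dens_l[[ti]] <- dens; rootd_l[[ti]] <- rd
    fromtip_l[[ti]] <- cl$from_tip_um; soil_l[[ti]] <- soil
    groups$rhizosphere_bulk[[ti]] <- classify_pixels(
      "rhizosphere_bulk", soil, root_dist_um = rd,
      centerline_dist_um = cl$centerline_dist_um,
      analysis_radius_um = qc$analysis_radius_um,
      bin_edges = c(0, qc$cutoff_um, Inf))
    groups$by_pore_size[[ti]] <- classify_pixels(
      "by_pore_size", soil, pore_size_um = pore_size)
    groups$tip_base[[ti]] <- classify_pixels(
      "tip_base", soil, tip_dist_um = cl$from_tip_um,
      bin_edges = c(0, qc$tip_base_cutoff_um, Inf))
    groups$by_root_distance[[ti]] <- classify_pixels(
      "by_root_distance", soil, root_dist_um = rd,
      centerline_dist_um = cl$centerline_dist_um,
      analysis_radius_um = qc$analysis_radius_um)
  }
  tip_edges <- seq(0, ceiling(max_tip / 500) * 500, by = 500)
  for (ti in seq_along(times))
    groups$by_tip_distance[[ti]] <- classify_pixels(
      "by_tip_distance", soil_l[[ti]], tip_dist_um = fromtip_l[[ti]],
      bin_edges = tip_edges)
  ind <- do.call(rbind, lapply(names(groups), function(s)
    compute_indicators(dens_l, groups[[s]], times,
                       discard_first = qc$discard_first)))
  kin <- kinematics_diagram(dens_l, fromtip_l, soil_l, times,
                            bin_um = qc$kinematics_bin_um,
                            discard_first = qc$discard_first)
  summ <- timeseries_summary(dens_l, rootd_l, soil_l, times,
                             cutoff_um = qc$cutoff_um)
  list(indicators = ind, kinematics = kin, summary = summ, calibration = calib,
       root_volumes_mm3 = root_vol, pore_size_um = pore_size,
       densities = dens_l, from_tip = fromtip_l, soil_masks = soil_l,
       root_dists = rootd_l, times_h = times)
}

#' Run the full pipeline from a configuration
#'
#' Simulate (phantom) -> reconstruct -> segment -> quantify, writing
#' indicator, kinematics and summary CSVs, the resolved configuration, and a
#' run manifest with file hashes to the output directory. Re-running with an
#' identical configuration and seed reproduces identical output hashes; if a
#' manifest from such a run already exists the computation is skipped.
#'
#' @param config A [pipeline_config()].
#' @param seed Optional seed override.
#' @param output_dir Optional output directory override.
#' @param force Recompute even when a matching manifest exists.
#' @return Invisibly, the run manifest (list).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         output_dir = NULL, force = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")
  man_path <- file.path(out, "run_manifest.yaml")
  cfg_hash <- digest_config(config)
  if (!force && file.exists(man_path)) {
    man <- yaml::read_yaml(man_path)
    if (identical(man$config_hash, cfg_hash) &&
        all(file.exists(file.path(out, names(man$files))))) {
      message("matching run manifest found; skipping recompute")
      return(invisible(man))
    }
  }
  if (!isTRUE(config$phantom$enabled))
    stop("stage 'simulate': only phantom-driven runs are supported without instrument tiles")
  pc <- config$phantom
  ph <- phantom_mesocosm(
    chamber = do.call(chamber_geometry, config$chamber),
    voxel_size_um = pc$voxel_size_um, target_porosity = pc$target_porosity,
    size_range_um = pc$size_range_um, root = pc$root,
    bacteria = do.call(bacteria_field_spec, pc$bacteria),
    calibration = pc$calibration, intensities = pc$intensities,
    times_h = pc$times_h, seed = config$seed)
  res <- analyze_phantom_series(ph, config)
  kin <- res$kinematics
  kin_df <- data.frame(
    bin_lo_um = rep(utils::head(kin$bin_edges_um, -1), length(kin$times_h)),
    timepoint_h = rep(kin$times_h, each = nrow(kin$matrix)),
    mean_density = as.vector(kin$matrix))
  meta <- list(seed = config$seed, units = "um, h, CFU/mL",
               package_version = as.character(utils::packageVersion("rhizolight")))
  write_table_csv(res$indicators, file.path(out, "indicators.csv"), meta)
  write_table_csv(kin_df, file.path(out, "kinematics.csv"), meta)
  write_table_csv(res$summary$series, file.path(out, "summary.csv"),
                  c(meta, list(peaks_h = as.list(res$summary$peaks_h))))
  write_config(config, cfg_path)
  files <- c("indicators.csv", "kinematics.csv", "summary.csv", "config.yaml")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  man <- list(format = "rhizolight-run-1", config_hash = cfg_hash,
              seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"),
              package_version = meta$package_version, files = hashes)
  yaml::write_yaml(man, man_path)
  invisible(man)
}

digest_config <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
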