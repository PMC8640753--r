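test_that("particle packing hits the target porosity and is deterministic", {
  ch <- chamber_geometry(2, 2, 2)
  p <- make_particle_packing(ch, c(250, 1250), 0.6, seed = 7)
  # analytic porosity from sphere volumes
  expect_equal(p$porosity, 0.6, tolerance = 0.02 / 0.6)
  expect_true(all(p$radii_um >= 125 & p$radii_um <= 625))
  # particles inside the domain and non-overlapping
  ext <- 1000 * c(2, 2, 2)
  expect_true(all(p$centers_um >= p$radii_um & p$centers_um <= rep(ext, each = nrow(p$centers_um)) - p$radii_um))
  dd <- as.matrix(dist(p$centers_um))
  rr <- outer(p$radii_um, p$radii_um, "+")
  diag(dd) <- Inf
  expect_true(all(dd >= rr - 1e-9))
  # voxel-count porosity oracle at 10 um
  m <- rasterize_packing(p, 10)
  expect_equal(1 - mean(m), 0.6, tolerance = 0.02 / 0.6)
  # determinism
  p2 <- make_particle_packing(ch, c(250, 1250), 0.6, seed = 7)
  expect_identical(p$centers_um, p2$centers_um)
  expect_identical(p$radii_um, p2$radii_um)
})

test_that("voxelized porosity matches analytic porosity within 2 percent", {
  for (tp in c(0.7, 0.9)) {
    p <- make_particle_packing(chamber_geometry(3, 3, 2), c(250, 1250), tp, seed = 2)
    m <- rasterize_packing(p, 10)
    expect_equal(1 - mean(m), p$porosity, tolerance = 0.02)
  }
})

test_that("edge porosities: empty packing, sparse packing, unreachable target", {
  expect_equal(make_particle_packing(chamber_geometry(2, 2, 2), target_porosity = 1)$porosity, 1)
  p <- make_particle_packing(chamber_geometry(22, 65, 3), c(250, 1250), 0.99, seed = 1)
  expect_gte(p$porosity, 0.99)
  expect_error(make_particle_packing(chamber_geometry(2, 2, 2), c(250, 1250), 0.05, seed = 1),
               "achieved")
})

test_that("root elongation follows the closed-form arc length", {
  r0 <- grow_root(c(1000, 500, 1000), radius_um = 250, elongation_rate_um_h = 0,
                  timepoint_h = 10, initial_length_um = 2000)
  expect_equal(r0$length_um, 2000)
  r1 <- grow_root(c(1000, 500, 1000), elongation_rate_um_h = 200, timepoint_h = 23,
                  initial_length_um = 2000)
  expect_equal(r1$length_um, 6600)
  expect_equal(root_length(r1), 6600, tolerance = 1e-9)
  expect_equal(unname(r1$tip_um[2]), 500 + 6600)
  r2 <- grow_root(c(1000, 500, 1000), timepoint_h = 0)
  expect_equal(r2$length_um, 2000)
  # truncation at the chamber boundary sets the flag
  expect_warning(
    r3 <- grow_root(c(1000, 500, 1000), elongation_rate_um_h = 1000, timepoint_h = 23,
                    chamber = chamber_geometry(2, 10, 2)),
    "truncated")
  expect_true(r3$truncated)
  expect_lte(r3$tip_um[2] + 250, 10000)
})

test_that("bacterial field: null configuration gives an all-zero field", {
  spec <- bacteria_field_spec(background_density = 0, root_accumulation_density = 0,
                              n_hotspots = 0, pore_bias_strength = 1)
  pore <- array(500, c(8, 8, 8))
  root <- array(FALSE, c(8, 8, 8))
  f <- bacteria_density_field(spec, root, pore, 50, timepoint_h = 5)
  expect_true(all(f == 0))
})

test_that("hotspot pulses follow the (t mod period) < duration schedule", {
  spec <- bacteria_field_spec(hotspot_period_h = 4, hotspot_duration_h = 2,
                              background_density = 0, root_accumulation_density = 0,
                              n_hotspots = 1, pore_bias_strength = 1,
                              bulk_peak_h = NA, rhizosphere_peak_h = NA)
  expect_true(hotspot_active(spec, 1))
  expect_false(hotspot_active(spec, 3))
  pore <- array(500, c(10, 10, 10))
  root <- array(FALSE, c(10, 10, 10))
  hs <- matrix(c(250, 250, 250), 1)
  for (t in 0:22) {
    f <- bacteria_density_field(spec, root, pore, 50, t, hotspots = hs)
    expect_identical(any(f > 0), (t %% 4) < 2, label = paste("t =", t))
  }
})

test_that("pore-size bias multiplies density below the threshold", {
  spec <- bacteria_field_spec(background_density = 1e6, root_accumulation_density = 0,
                              n_hotspots = 0, pore_bias_strength = 3,
                              pore_bias_threshold_um = 400, bulk_peak_h = NA)
  pore <- array(rep(c(200, 600), each = 500), c(10, 10, 10))
  root <- array(FALSE, c(10, 10, 10))
  f <- bacteria_density_field(spec, root, pore, 50, 5)
  expect_equal(mean(f[pore < 400]) / mean(f[pore >= 400]), 3, tolerance = 1e-12)
})

test_that("bacterial field rejects mismatched grids", {
  spec <- bacteria_field_spec(n_hotspots = 0)
  expect_error(
    bacteria_density_field(spec, array(FALSE, c(4, 4, 4)), array(1, c(4, 4, 5)), 50, 1),
    "grid mismatch")
})

test_that("identity forward model returns exact crops of the truth", {
  tb <- balls_truth()
  scn <- scan_geometry(scan_angle_deg = 0, tile_grid = c(1, 1),
                       chamber = chamber_geometry(1.2, 2, 1.2))
  tiles <- render_scan(tb$volume, scn, optics = NULL)
  expect_length(tiles, 1)
  expect_same_array(tiles[[1]]$frames, tb$volume$channels$particle)
})

test_that("rendering is bit-identical under a fixed seed", {
  tb <- balls_truth()
  scn <- scan_geometry(scan_angle_deg = 45, tile_grid = c(2, 1),
                       tile_overlap_fraction = 0.2, chamber = chamber_geometry(1.2, 2, 1.2))
  noi <- noise_model(read_noise_sd = 2, vignetting_min = 0.7, rng_seed = 42)
  t1 <- render_scan(tb$volume, scn, optics = NULL, noise = noi)
  t2 <- render_scan(tb$volume, scn, optics = NULL, noise = noi)
  for (i in seq_along(t1)) expect_identical(t1[[i]]$frames, t2[[i]]$frames)
})

test_that("a point source renders with the configured axial FWHM", {
  dims <- c(41L, 41L, 41L)
  a <- array(0, dims); a[21, 21, 21] <- 1
  tr <- volume_image(list(gfp = a), 25)
  scn <- scan_geometry(scan_angle_deg = 0, chamber = chamber_geometry(41 * .025, 41 * .025, 41 * .025))
  tiles <- render_scan(tr, scn, optics = optics_model(sheet_fwhm_um = 50, lateral_fwhm_um = 50))
  raw <- tiles[[1]]$frames
  prof <- raw[, 21, 21]  # axial profile through the blob
  expect_equal(profile_fwhm(prof, 25), 50, tolerance = 5 / 50)
})

test_that("the 45-degree scan displaces content by step/sqrt(2) per slice", {
  dims <- c(24L, 40L, 24L)
  a <- array(0, dims)
  a <- a + 600 * ball_mask(dims, c(12, 20, 12), 4)
  tr <- volume_image(list(particle = a), 50)
  scn <- scan_geometry(scan_angle_deg = 45, chamber = chamber_geometry(1.2, 2, 1.2))
  tiles <- render_scan(tr, scn, optics = NULL)
  raw <- tiles[[1]]$frames
  step <- tiles[[1]]$slice_step_um
  rows <- vapply(seq_len(dim(raw)[1]), function(k) {
    s <- raw[k, , ]
    if (sum(s) == 0) NA_real_ else sum(row(s) * s) / sum(s)
  }, 0)
  ks <- which(!is.na(rows))
  drift <- stats::coef(stats::lm(rows[ks] ~ ks))[2] * 50  # um per slice
  expect_equal(unname(abs(drift)), step / sqrt(2), tolerance = 0.02)
})
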