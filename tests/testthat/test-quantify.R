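test_that("distance from root: unit step, brute force, analytic ball", {
  dims <- c(12L, 12L, 12L)
  root <- array(FALSE, dims); root[6, 6, 6] <- TRUE
  d <- distance_from_root(root, 50)
  expect_equal(d[6, 7, 6], 50)
  expect_equal(d[6, 6, 6], 0)
  # exact match with the brute-force oracle on random masks
  set.seed(13)
  for (rep in 1:5) {
    m <- array(runif(prod(dims)) < 0.04, dims)
    if (!any(m)) m[2, 3, 4] <- TRUE
    sp <- sample(c(10, 25, 50), 3, replace = TRUE)
    expect_equal(as.vector(distance_from_root(m, sp)),
                 as.vector(edt_bruteforce(m, sp)), tolerance = 1e-12)
  }
  # ball root of radius r: outside distance is d - r within one voxel
  dims2 <- c(24L, 24L, 24L)
  ball <- ball_mask(dims2, c(12, 12, 12), 5)
  dmap <- distance_from_root(ball, 50)
  probe <- c(12, 12, 22)  # 10 voxels from the centre
  expect_equal(dmap[12, 12, 22], (10 - 5) * 50, tolerance = 50)
  expect_error(distance_from_root(array(FALSE, c(4, 4, 4)), 50), "empty")
})

test_that("centerline and tip on straight and curved tubes", {
  dims <- c(20L, 60L, 20L)
  cyl <- cylinder_mask(dims, c(10, 10), 4, c(6, 55))
  cl <- centerline_and_tip(cyl, 50)
  # apex-to-apex geodesic length of a 50-voxel cylinder
  expect_equal(cl$length_um, 49 * 50, tolerance = 100)
  expect_equal(unname(cl$tip_um[2]), 54 * 50, tolerance = 100)
  # voxel beside the tip has from_tip near zero
  expect_lt(cl$from_tip_um[10, 55, 15], 300)
  # a quarter-circle tube of known arc length
  dims2 <- c(16L, 44L, 44L)
  R <- 30
  idx <- arrayInd(seq_len(prod(dims2)), dims2)
  rad <- sqrt((idx[, 2] - 5)^2 + (idx[, 3] - 5)^2)
  ang <- atan2(idx[, 3] - 5, idx[, 2] - 5)
  tube <- array(abs(rad - R) <= 3 & ang >= 0 & ang <= pi / 2 & abs(idx[, 1] - 8) <= 3, dims2)
  cl2 <- centerline_and_tip(tube, 50, base_um = c(8, 35, 5) * 50)
  expect_equal(cl2$length_um, (pi / 2) * R * 50, tolerance = 0.05 * (pi / 2) * R * 50)
  expect_error(centerline_and_tip(array(FALSE, c(4, 4, 4)), 50), "empty")
})

test_that("calibration fits recover exact and noisy synthetic lines", {
  od <- exp(seq(log(1.2e-3), log(3), length.out = 12))
  standards <- data.frame(intensity = 1000 * od + 50, od600 = od)
  cfu <- data.frame(od600 = od, cfu = 2e8 * od)
  fit <- fit_calibration(standards, cfu)
  expect_equal(fit$intensity_per_od, 1000, tolerance = 1e-6)
  expect_equal(fit$intensity_offset, 50, tolerance = 1e-6)
  expect_equal(fit$cfu_per_od, 2e8, tolerance = 1e-6)
  # constant intensity cannot calibrate
  expect_error(fit_calibration(data.frame(intensity = rep(5, 12), od600 = od), cfu),
               "calibration error")
  # narrow OD span is rejected
  expect_error(fit_calibration(data.frame(intensity = od + 1, od600 = od * 0 + c(1, 2, 3)),
                               cfu), "decade")
  # 1% multiplicative noise keeps slopes within 5%
  truth <- list(intensity_per_od = 1000, intensity_offset = 50, cfu_per_od = 2e8)
  for (s in 1:20) {
    sim <- simulate_calibration(truth, seed = s)
    f <- fit_calibration(sim$standards, sim$cfu_points)
    expect_equal(f$intensity_per_od, 1000, tolerance = 0.05)
    expect_equal(f$cfu_per_od, 2e8, tolerance = 0.05)
  }
})

test_that("intensity-to-density conversion inverts the forward model", {
  fit <- structure(list(intensity_per_od = 1000, intensity_offset = 50,
                        cfu_per_od = 2e8), class = "calibration_model")
  expect_equal(as.vector(intensity_to_density(array(50, c(2, 2, 2)), fit)), rep(0, 8))
  expect_equal(as.vector(intensity_to_density(array(1050, c(1, 1, 1)), fit)), 2e8)
  # forward-model round trip on a phantom truth channel (ideal optics)
  ch <- chamber_geometry(2, 6, 1.5)
  ph <- phantom_mesocosm(ch, voxel_size_um = 50, times_h = 21, seed = 5)
  tr <- phantom_truth(ph, 21)
  scn <- scan_geometry(scan_angle_deg = 45, chamber = ch)
  tiles <- render_scan(tr$volume, scn, optics = NULL)
  rec <- reconstruct_volume(tiles, flatfield = FALSE, optics = NULL, crop_to = tr$volume)
  dens <- intensity_to_density(vol_channel(rec, "gfp"), fit)
  rel_rms <- sqrt(mean((dens - tr$density)^2)) / sqrt(mean(tr$density^2))
  expect_lt(rel_rms, 0.02)
})

test_that("pixel classification follows the stated cutoffs and conventions", {
  d <- c(4L, 4L, 4L)
  soil <- array(TRUE, d)
  rd <- array(150, d); cd <- array(0, d)
  g <- classify_pixels("rhizosphere_bulk", soil, root_dist_um = rd, centerline_dist_um = cd)
  expect_true(all(g$group == 1))
  expect_equal(g$labels, c("rhizosphere", "bulk"))
  td <- array(2500, d)
  g2 <- classify_pixels("tip_base", soil, tip_dist_um = td)
  expect_true(all(g2$group == 2))  # base: more than 2 mm from the tip
  ps <- array(400, d)
  g3 <- classify_pixels("by_pore_size", soil, pore_size_um = ps, bin_edges = c(0, 400, 800))
  expect_true(all(g3$group == 2))  # half-open bins: boundary falls upward
  expect_error(classify_pixels("by_pore_size", soil, pore_size_um = ps,
                               bin_edges = c(0, 800, 400)), "increasing")
  # radial restriction to the 3 mm cylinder
  cd2 <- array(2000, d)
  g4 <- classify_pixels("rhizosphere_bulk", soil, root_dist_um = rd, centerline_dist_um = cd2)
  expect_true(all(is.na(g4$group)))
})

test_that("groups partition the analyzed soil volume", {
  set.seed(17)
  d <- c(10L, 10L, 10L)
  soil <- array(runif(prod(d)) < 0.7, d)
  ps <- array(runif(prod(d), 0, 900), d)
  g <- classify_pixels("by_pore_size", soil, pore_size_um = ps,
                       bin_edges = c(0, 300, 600, Inf))
  expect_equal(sum(!is.na(g$group)), sum(soil))
  expect_true(all(is.na(g$group[!soil])))
})

test_that("indicators: uniform field, hand-computed two-group case, normalization", {
  d <- c(6L, 8L, 6L)
  soil <- array(TRUE, d)
  ps <- array(rep(c(200, 600), each = prod(d) / 2), d)
  grp <- classify_pixels("by_pore_size", soil, pore_size_um = ps, bin_edges = c(0, 400, 800))
  times <- 1:8
  # uniform density: D_norm = 1 everywhere, variance 0
  uni <- lapply(times, function(t) array(5e6, d))
  tab <- compute_indicators(uni, grp, times)
  expect_true(all(abs(tab$D_norm - 1) < 1e-12))
  expect_true(all(tab$variance == 0))
  # densities 2x and x in equal volumes: D_norm = 4/3 and 2/3
  dens <- lapply(times, function(t) { a <- array(1e6, d); a[ps < 400] <- 2e6; a })
  tab2 <- compute_indicators(dens, grp, times)
  expect_equal(unique(round(tab2$D_norm[tab2$group_id == 1], 10)), 4 / 3)
  expect_equal(unique(round(tab2$D_norm[tab2$group_id == 2], 10)), 2 / 3)
  # normalization invariant on random fields
  set.seed(23)
  rnd <- lapply(times, function(t) array(runif(prod(d), 1e5, 1e7), d))
  tab3 <- compute_indicators(rnd, grp, times)
  means <- tapply(tab3$D_norm, tab3$timepoint_h, mean)
  expect_true(all(abs(means - 1) < 1e-9))
  # per-root-volume flag rescales D but not D_norm
  tab4 <- compute_indicators(dens, grp, times, root_volume_mm3 = rep(2, 8))
  expect_equal(tab4$D, tab2$D / 2)
  expect_equal(tab4$D_norm, tab2$D_norm)
})

test_that("empty groups are flagged with zero counts", {
  d <- c(4L, 4L, 4L)
  soil <- array(TRUE, d)
  ps <- array(100, d)
  grp <- classify_pixels("by_pore_size", soil, pore_size_um = ps, bin_edges = c(0, 400, 800))
  tab <- compute_indicators(list(array(1e6, d)), grp, times_h = 1)
  expect_equal(tab$voxel_count[tab$group_id == 2], 0)
  expect_true(is.na(tab$D[tab$group_id == 2]))
})

test_that("kinematics diagram: static and moving stripes, pulse autocorrelation", {
  vs <- 50
  dims <- c(16L, 200L, 16L)
  ch <- chamber_geometry(0.8, 10, 0.8)
  times <- 20:42
  blob_y <- 50  # lab-frame-fixed hotspot voxel row
  mk_series <- function(rate) {
    dens <- list(); ftip <- list(); soil <- list()
    for (i in seq_along(times)) {
      root <- rasterize_root(grow_root(c(400, 100, 400), radius_um = 150,
                                       elongation_rate_um_h = rate,
                                       timepoint_h = times[i], initial_length_um = 1000,
                                       chamber = ch, node_step_um = 50), vs, dims)
      cl <- centerline_and_tip(root, vs)
      a <- array(0, dims)
      a[8, blob_y + (-2:2), 12] <- 1e7
      dens[[i]] <- a; ftip[[i]] <- cl$from_tip_um; soil[[i]] <- !root
    }
    kinematics_diagram(dens, ftip, soil, times, bin_um = 250)
  }
  # static root: horizontal stripe
  kin0 <- mk_series(0)
  pos0 <- apply(kin0$matrix, 2, which.max)
  expect_true(all(pos0 == pos0[1]))
  # elongating root: stripe slope matches the elongation rate within 10%
  kin <- mk_series(150)
  expect_equal(stripe_slope(kin), 150, tolerance = 0.10)
  # pulsed amplitude: autocorrelation recovers the 4 h period
  pulsed <- lapply(times, function(t) {
    a <- array(0, dims)
    a[8, blob_y + (-2:2), 12] <- 1e7 * (1 + ((t %% 4) < 2))
    a
  })
  root0 <- rasterize_root(grow_root(c(400, 100, 400), radius_um = 150,
                                    elongation_rate_um_h = 0, timepoint_h = 0,
                                    initial_length_um = 1000, chamber = ch), vs, dims)
  cl0 <- centerline_and_tip(root0, vs)
  kin2 <- kinematics_diagram(pulsed, rep(list(cl0$from_tip_um), length(times)),
                             !root0, times, bin_um = 250)
  series <- kin2$matrix[which.max(rowMeans(kin2$matrix, na.rm = TRUE)), ]
  expect_equal(estimate_pulse_period(series), 4, tolerance = 0.25)
  expect_error(kinematics_diagram(pulsed, rep(list(cl0$from_tip_um), length(times)),
                                  !root0, rev(times)), "increasing")
})

test_that("time-series summary partitions soil and detects programmed peaks", {
  d <- c(8L, 8L, 8L)
  times <- 1:10
  root <- array(FALSE, d); root[4, 4, 4] <- TRUE
  rd <- distance_from_root(root, 50)
  soil <- !root
  # constant field: flat curves and exact volume weighting
  dens <- lapply(times, function(t) array(3e6, d))
  ts <- timeseries_summary(dens, rep(list(rd), 10), soil, times)
  expect_true(all(abs(ts$series$rhizosphere - 3e6) < 1e-6))
  with(ts$series, expect_equal(total * (n_rhizosphere + n_bulk),
                               rhizosphere * n_rhizosphere + bulk * n_bulk))
  expect_equal(ts$series$n_rhizosphere + ts$series$n_bulk, rep(sum(soil), 10))
  # programmed peaks recovered at the right time step
  dens2 <- lapply(times, function(t) {
    a <- array(exp(-(t - 4)^2 / 4), d)          # bulk peak at t = 4
    a[rd < 200] <- 2 * exp(-(t - 7)^2 / 4)      # rhizosphere peak at t = 7
    a * 1e6
  })
  ts2 <- timeseries_summary(dens2, rep(list(rd), 10), soil, times)
  expect_equal(unname(ts2$peaks_h["bulk"]), 4)
  expect_equal(unname(ts2$peaks_h["rhizosphere"]), 7)
})
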