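test_that("shear correction at 0 degrees is the identity", {
  tb <- balls_truth()
  scn <- scan_geometry(scan_angle_deg = 0, chamber = chamber_geometry(1.2, 2, 1.2))
  tile <- render_scan(tb$volume, scn, optics = NULL)[[1]]
  v <- shear_correct(tile)
  expect_same_array(vol_channel(v), tb$volume$channels$particle)
})

test_that("shear correction recovers phantom centroids within one voxel", {
  tb <- balls_truth(n = 5)
  scn <- scan_geometry(scan_angle_deg = 45, chamber = chamber_geometry(1.2, 2, 1.2))
  tile <- render_scan(tb$volume, scn, optics = NULL)[[1]]
  v <- shear_correct(tile)
  rec <- vol_channel(v)
  off <- round(v$origin_um / 50)  # negative y origin from the shear span
  for (i in seq_len(nrow(tb$centers))) {
    ctr <- tb$centers[i, ]
    win <- lapply(1:3, function(a) (ctr[a] - 4):(ctr[a] + 4) - off[a])
    sub <- rec[win[[1]], win[[2]], win[[3]]]
    sub[is.na(sub)] <- 0
    est <- weighted_centroid(sub) + c(win[[1]][1], win[[2]][1], win[[3]][1]) - 1 + off
    expect_lt(sqrt(sum((est - ctr)^2)), 1)
  }
})

test_that("shear round trip correlates at 0.99 outside fill regions", {
  tb <- balls_truth()
  scn <- scan_geometry(scan_angle_deg = 45, chamber = chamber_geometry(1.2, 2, 1.2))
  tile <- render_scan(tb$volume, scn, optics = NULL)[[1]]
  v <- shear_correct(tile)
  arr <- vol_channel(v)
  valid <- !is.na(arr)
  arr[!valid] <- 0
  # re-render the corrected volume through the same 45-degree shear: frame
  # (k, v, u) samples volume row v + k (one-voxel shear per slice)
  d0 <- dim(tile$frames)
  r2 <- rhizolight:::cpp_sample_sheared(arr, dim(arr), d0[1], d0[2], d0[3],
                                        0, 0, 0, 1, 1)
  dim(r2) <- d0
  ok <- rhizolight:::cpp_sample_sheared(valid + 0, dim(arr), d0[1], d0[2], d0[3],
                                        0, 0, 0, 1, 1) > 0.5
  expect_gt(cor(as.vector(tile$frames[ok]), as.vector(r2[ok])), 0.99)
})

test_that("flat-field estimation: constant frames give unit weights", {
  fr <- array(7, c(20, 20, 10))
  ff <- estimate_flatfield(fr)
  expect_equal(ff$weight_matrix, matrix(1, 20, 20))
  expect_error(estimate_flatfield(array(0, c(20, 20, 10))), "degenerate")
})

test_that("flat-field estimation recovers a known vignetting field", {
  # a particle packing provides the repeating soil texture the estimator needs
  p <- make_particle_packing(chamber_geometry(2, 3, 1.5), c(250, 1250), 0.6, seed = 6)
  a <- rasterize_packing(p, 50)
  tr <- volume_image(list(particle = 600 * a), 50)
  scn <- scan_geometry(scan_angle_deg = 0, chamber = chamber_geometry(2, 3, 1.5))
  noi <- noise_model(vignetting_min = 0.6)
  tiles <- render_scan(tr, scn, optics = NULL, noise = noi)
  ff <- estimate_flatfield(tiles[[1]])
  V <- vignetting_field(noi, dim(tiles[[1]]$frames)[2], dim(tiles[[1]]$frames)[3])
  expect_gt(cor(as.vector(1 / ff$weight_matrix), as.vector(V)), 0.95)
})

test_that("flat-field correction flattens textured frames", {
  # checkerboard texture times a vignetting ramp
  H <- 48L; W <- 48L; FF <- 12L
  cb <- 100 + 400 * (outer(1:H, 1:W, "+") %% 2)
  V <- vignetting_field(noise_model(vignetting_min = 0.6), H, W)
  fr <- array(rep(cb * V, FF), c(H, W, FF))
  ff <- estimate_flatfield(fr)
  corrected <- apply_flatfield(
    volume_image(list(value = aperm(fr, c(3, 1, 2))), 50), ff, pyramid_levels = 1)
  cv <- function(x) sd(x) / mean(x)
  cv_before <- cv(colMeans(fr[, , 1]))
  cv_after <- cv(colMeans(vol_channel(corrected)[1, , ]))
  expect_gt(cv_before / cv_after, 5)
})

test_that("flat-field application: identity weights, inverse field, one level", {
  set.seed(2)
  f <- matrix(runif(40 * 32, 50, 500), 40, 32)
  vol <- volume_image(list(value = array(f, c(1, 40, 32))), 50)
  id <- structure(list(weight_matrix = matrix(1, 40, 32), mode_reference = 1,
                       neighborhood_px = 9, bin_width = 1, clip = c(0.2, 5)),
                  class = "flatfield_model")
  expect_same_array(vol_channel(apply_flatfield(vol, id, pyramid_levels = 4)), f, tol = 1e-9)
  # flat frame times V corrected with weights 1/V comes back flat within 2%
  V <- vignetting_field(noise_model(vignetting_min = 0.6), 40, 32)
  flat <- volume_image(list(value = array(300 * V, c(1, 40, 32))), 50)
  inv <- id; inv$weight_matrix <- 1 / V
  out <- vol_channel(apply_flatfield(flat, inv, pyramid_levels = 3))
  expect_lt(max(abs(out - 300)) / 300, 0.02)
  # one pyramid level equals plain multiplication
  w <- id; w$weight_matrix <- matrix(runif(40 * 32, 0.5, 2), 40, 32)
  expect_same_array(vol_channel(apply_flatfield(vol, w, pyramid_levels = 1)),
                    f * w$weight_matrix)
  # shape mismatch errors
  bad <- id; bad$weight_matrix <- matrix(1, 10, 10)
  expect_error(apply_flatfield(vol, bad), "shape mismatch")
})

test_that("light-sheet PSF is normalized with the configured widths", {
  psf <- make_lightsheet_psf(optics_model(sheet_fwhm_um = 50, lateral_fwhm_um = 50), 25)
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-6)
  expect_true(all(psf$kernel >= 0))
  # isotropic kernel is symmetric under axis permutation
  expect_equal(psf$kernel, aperm(psf$kernel, c(2, 1, 3)), tolerance = 1e-12)
  # axial FWHM of 2 voxels at 25 um voxels
  prof <- psf$sep$kz
  expect_equal(profile_fwhm(prof), 2, tolerance = 0.1)
  expect_error(make_lightsheet_psf(optics_model(sheet_fwhm_um = 10), 25), "undersampling")
})

test_that("Richardson-Lucy: delta PSF fixed point, contrast gain, monotone likelihood", {
  set.seed(9)
  dims <- c(20L, 20L, 20L)
  a <- array(0, dims); a[10, 10, 10] <- 100
  expect_same_array(lr_deconvolve(a, psf_delta(), 7), a)
  psf <- make_lightsheet_psf(optics_model(100, 100), 50)
  blurred <- conv_sep3(a + 1, psf$sep$kz, psf$sep$ky, psf$sep$kx)
  dec <- lr_deconvolve(blurred, psf, 20, track_likelihood = TRUE)
  expect_true(all(dec >= 0))
  expect_equal(sum(dec), sum(blurred), tolerance = 0.01)
  expect_gt(max(dec) / mean(dec), max(blurred) / mean(blurred))
  ll <- attr(dec, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
  bad <- a; bad[1, 1, 1] <- -1
  expect_error(lr_deconvolve(bad, psf), "negative")
})

test_that("stitching: identity blend, offset recovery, seams, order independence", {
  tb <- balls_truth(dims = c(20L, 48L, 32L), n = 6, seed = 8)
  truth <- tb$volume$channels$particle
  mk <- function(ylim, xlim, origin_shift = c(0, 0, 0), ramp = 1) {
    a <- truth[, ylim[1]:ylim[2], xlim[1]:xlim[2], drop = FALSE] * ramp
    volume_image(list(particle = a), 50,
                 origin_um = (c(0, ylim[1], xlim[1]) - 1 + origin_shift) * 50)
  }
  # identical tiles at zero offset blend to the tile itself
  t1 <- mk(c(1, 48), c(1, 32)); t2 <- mk(c(1, 48), c(1, 32))
  out <- stitch_tiles(list(t1, t2), search_radius = 0)
  expect_equal(as.vector(vol_channel(out)), as.vector(truth), tolerance = 1e-9)
  # 2x2 tiles with 25% overlap; one tile origin corrupted by 2 voxels is
  # recovered exactly by registration
  tiles <- list(mk(c(1, 28), c(1, 20)), mk(c(21, 48), c(1, 20)),
                mk(c(1, 28), c(13, 32)), mk(c(21, 48), c(13, 32), origin_shift = c(0, 2, -1)))
  out2 <- stitch_tiles(tiles, search_radius = 5)
  expect_identical(vol_dim(out2), dim(truth))
  expect_gt(cor(as.vector(vol_channel(out2)), as.vector(truth)), 0.99)
  # a 10% intensity ramp mismatch leaves no seam discontinuity above 2%
  ta <- mk(c(1, 28), c(1, 32)); tbb <- mk(c(21, 48), c(1, 32), ramp = 1.1)
  out3 <- stitch_tiles(list(ta, tbb), search_radius = 0)
  v <- vol_channel(out3)
  jumps <- abs(apply(v, 2, mean)[-1] - apply(v, 2, mean)[-48])
  expect_lt(max(jumps[20:30]) , 0.02 * diff(range(truth)))
  # input order changes no output voxel
  out4 <- stitch_tiles(rev(tiles), search_radius = 5)
  expect_identical(vol_channel(out4), vol_channel(out2))
  # non-overlapping tiles raise a stitching error
  expect_error(stitch_tiles(list(mk(c(1, 20), c(1, 32)), mk(c(29, 48), c(1, 32))),
                            search_radius = 5), "stitching error")
})

test_that("noise-free full chain conserves total intensity within 1 percent", {
  ch <- chamber_geometry(1.5, 2.5, 1)
  tb <- balls_truth(dims = c(20L, 50L, 30L), n = 8, seed = 12, channel = "gfp")
  scn <- scan_geometry(scan_angle_deg = 45, tile_grid = c(2, 1),
                       tile_overlap_fraction = 0.25, chamber = ch)
  tiles <- render_scan(tb$volume, scn, optics = optics_model(50, 50))
  rec <- reconstruct_volume(tiles, flatfield = FALSE, optics = NULL, crop_to = tb$volume)
  expect_equal(sum(vol_channel(rec), na.rm = TRUE), sum(tb$volume$channels$gfp),
               tolerance = 0.01)
})
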