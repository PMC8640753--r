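test_that("chamber volume follows the cuboid dimensions", {
  expect_equal(chamber_volume(chamber_geometry(22, 65, 3)), 4290)
  expect_equal(chamber_volume(chamber_geometry(2, 2, 2)), 8)
  expect_error(chamber_geometry(0, 65, 3))
})

test_that("imaged volume is the scan footprint clipped to the chamber depth", {
  scn <- scan_geometry(footprint_mm = c(60, 20), chamber = chamber_geometry(22, 65, 3))
  expect_equal(imaged_volume(scn), 3600)
  expect_equal(imaged_volume(scan_geometry(footprint_mm = c(10, 10),
                                           chamber = chamber_geometry(5, 5, 2))), 200)
})

test_that("scan geometry validates overlap and angle", {
  expect_error(scan_geometry(tile_overlap_fraction = 1), "overlap")
  expect_error(scan_geometry(tile_overlap_fraction = -0.1), "overlap")
  expect_error(scan_geometry(scan_angle_deg = NA), "angle")
})

test_that("vignetting field is smooth, 1 at centre, minimum at corners", {
  noi <- noise_model(vignetting_min = 0.6)
  v <- vignetting_field(noi, 41, 31)
  expect_equal(max(v), 1)
  expect_equal(v[1, 1], 0.6, tolerance = 1e-12)
  expect_equal(v[41, 31], 0.6, tolerance = 1e-12)
  expect_true(all(v > 0 & v <= 1))
  expect_equal(vignetting_field(noise_model(), 10, 10), matrix(1, 10, 10))
})
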