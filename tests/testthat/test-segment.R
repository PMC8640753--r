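test_that("region growing recovers a bright cylinder exactly", {
  dims <- c(24L, 40L, 24L)
  cyl <- cylinder_mask(dims, c(12, 12), 4, c(5, 35))
  vol <- array(0, dims); vol[cyl] <- 1000
  m <- segment_root(vol, matrix(c(12, 20, 12), 1), threshold = 500)
  expect_identical(as.vector(m), as.vector(cyl))
})

test_that("region growing rejects seeds below threshold", {
  vol <- array(10, c(8, 8, 8))
  expect_error(segment_root(vol, matrix(c(4, 4, 4), 1), threshold = 1e6), "seed error")
})

test_that("region growing keeps only the seeded component", {
  dims <- c(20L, 20L, 20L)
  b1 <- ball_mask(dims, c(6, 6, 6), 3)
  b2 <- ball_mask(dims, c(15, 15, 15), 3)
  vol <- array(0, dims); vol[b1 | b2] <- 100
  m <- segment_root(vol, matrix(c(6, 6, 6), 1), threshold = 50, closing_radius = 0)
  expect_identical(as.vector(m), as.vector(b1))
})

test_that("pore segmentation: empty scene, phantom packing, degenerate GFP", {
  # no particles and no root: everything is pore space
  empty <- segment_pores(array(0, c(10, 10, 10)), array(0, c(10, 10, 10)))
  expect_true(all(empty))
  # phantom packing against the true pore mask
  p <- make_particle_packing(chamber_geometry(2.5, 2.5, 1.5), c(250, 1250), 0.6, seed = 4)
  pm <- rasterize_packing(p, 50)
  particle_ch <- 600 * pm
  gfp_ch <- array(80, dim(pm)); gfp_ch[!pm] <- 120  # bacteria in pores
  pores <- segment_pores(particle_ch, gfp_ch)
  truep <- !pm
  expect_gt(sum(pores & truep) / sum(pores | truep), 0.97)
  # constant GFP falls back to particle-only segmentation
  pores2 <- segment_pores(particle_ch, array(5, dim(pm)), threshold = 0.5)
  pores3 <- segment_pores(particle_ch, NULL, threshold = 0.5)
  expect_identical(pores2, pores3)
})

test_that("local thickness matches analytic ball and slab values", {
  dims <- c(30L, 30L, 30L)
  vs <- 20
  ball <- ball_mask(dims, c(15, 15, 15), 10)  # diameter 400 um at 20 um voxels
  lt <- local_thickness(ball, vs)
  inside <- lt[ball]
  expect_true(all(abs(inside - 400) <= 2 * vs + 1e-9))
  expect_true(all(lt[!ball] == 0))
  # slab of thickness 8 voxels = 160 um
  slab <- array(FALSE, dims); slab[, , 10:17] <- TRUE
  lts <- local_thickness(slab, vs)
  core <- lts[15, 15, 10:17]
  expect_true(all(abs(core - 160) <= vs + 1e-9))
  # empty mask warns and returns zeros
  expect_warning(z <- local_thickness(array(FALSE, c(4, 4, 4)), vs), "empty")
  expect_true(all(z == 0))
})

test_that("local thickness is monotone under erosion of the pore mask", {
  set.seed(21)
  dims <- c(16L, 16L, 16L)
  pore <- array(runif(prod(dims)) < 0.7, dims)
  lt1 <- local_thickness(pore, 10)
  er <- rhizolight:::cpp_morph(pore, dims, 1L, FALSE)
  dim(er) <- dims
  if (any(er)) {
    lt2 <- local_thickness(er, 10)
    expect_true(all(lt2 <= lt1 + 1e-9))
  }
})

test_that("local thickness equals exhaustive brute force on small masks", {
  set.seed(31)
  for (rep in 1:6) {
    dims <- c(14L, 14L, 14L)
    pore <- array(runif(prod(dims)) < runif(1, 0.3, 0.7), dims)
    sp <- sample(c(10, 20, 50), 3, replace = TRUE)
    expect_equal(as.vector(local_thickness(pore, sp)),
                 as.vector(lt_bruteforce(pore, sp)), tolerance = 1e-12)
  }
})
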