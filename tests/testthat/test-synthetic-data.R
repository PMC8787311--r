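test_that("spindle generator is deterministic and honours its parameters", {
  p <- spindle_params(soma_length = 37, soma_diameter = 19, seed = 7)
  m1 <- generate_spindle_swc(p)
  m2 <- generate_spindle_swc(p)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_swc(m1, f1); write_swc(m2, f2)
  expect_identical(readLines(f1), readLines(f2))      # byte-identical SWC

  sm <- soma_metrics(m1)
  expect_equal(sm$soma_length, 37)
  expect_equal(sm$soma_max_diameter, 19)
  sm2 <- soma_metrics(generate_spindle_swc(spindle_params(41, 16, seed = 8)))
  expect_equal(sm2$soma_length, 41)
  expect_equal(sm2$soma_max_diameter, 16)
  expect_equal(sm2$soma_volume, (4 / 3) * pi * (41 / 2) * (16 / 2)^2)

  # straight profile: exactly two dendritic tips (no collaterals)
  ms <- generate_spindle_swc(spindle_params(branch_profile = "straight", seed = 4))
  pidx <- match(ms$parent, ms$id)
  dend <- ms$type == 3L
  nch <- tabulate(pidx[dend], nbins = nrow(ms))
  tips <- sum(dend & nch[seq_len(nrow(ms))] == 0)
  expect_identical(tips, 2L)

  expect_error(spindle_params(soma_length = 10, soma_diameter = 19), "soma_length")
  expect_error(spindle_params(total_extent = 20), "total_extent")
})

test_that("spine decoration follows density, mix and the declared invariants", {
  seg <- straight_segment(40, n = 81)
  expect_identical(nrow(decorate_with_spines(seg, 0, seed = 1)$spines), 0L)

  tr <- decorate_with_spines(seg, 0.5, class_mix = c(mushroom = 1), seed = 2)
  expect_true(all(tr$spines$class_label == "mushroom"))
  # count recorded in the truth equals the realised point process count,
  # with Poisson expectation density * length = 20
  expect_equal(nrow(tr$spines), round(tr$density_per_um * tr$decorated_length))
  counts <- vapply(1:30, function(s) {
    nrow(decorate_with_spines(seg, 0.5, seed = s)$spines)
  }, 0L)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 30))

  # attachments lie on the shaft surface (radius 0.4 from the axis)
  rad <- sqrt((tr$spines$attach_y - 4)^2 + (tr$spines$attach_z - 4)^2)
  expect_true(all(abs(rad - 0.4) < 1e-9))
  expect_error(decorate_with_spines(seg, 0.5, class_mix = c(mushroom = 0.7)),
               "class_mix")

  # determinism
  t1 <- decorate_with_spines(seg, 0.8, seed = 11)
  t2 <- decorate_with_spines(seg, 0.8, seed = 11)
  expect_equal(t1$spines, t2$spines)
})

test_that("empirical class frequencies recover the configured mix", {
  seg <- spindlemorph:::segment_phantom(75)
  mix <- c(thin = 0.25, stubby = 0.20, wide = 0.15, mushroom = 0.30, ramified = 0.10)
  tr <- decorate_with_spines(seg, density_per_um = 8, class_mix = mix, seed = 7)
  n <- nrow(tr$spines)
  expect_gte(n, 500)
  freq <- table(factor(tr$spines$class_label, levels = names(mix))) / n
  z <- (as.numeric(freq) - mix) / sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(z) < 3))
})

test_that("rendering voxelizes geometry exactly and obeys the render contract", {
  # straight 1 um-diameter cylinder: voxel mask matches the analytic
  # point-in-capsule test exactly
  seg <- straight_segment(8, radius = 0.5, n = 2, origin = c(1, 4, 4))
  tr <- bare_truth(seg)
  sp <- voxel_spacing(0.1)
  mask <- voxelize_truth(tr, sp, extent = c(10, 8, 8), origin = c(0, 0, 0))
  oracle <- oracle_capsule_mask(c(1, 4, 4), c(9, 4, 4), 0.5, sp, c(10, 8, 8))
  expect_identical(mask$mask, oracle)

  # no geometry, no noise -> constant stack at bg_level
  empty <- binary_volume(array(FALSE, c(10, 10, 5)), sp)
  st0 <- render_stack(tr, sp, psf_sigma_xy = 0, psf_sigma_z = 0, bg_level = 200,
                      fg_level = 60, seed = 1, mask = empty)
  expect_true(all(st0$voxels == 200))

  # slice-count convention: floor(extent/dz) + 1
  st15 <- render_stack(tr, voxel_spacing(0.1, 0.1, 0.1), psf_sigma_xy = 0,
                       psf_sigma_z = 0, seed = 1, extent = c(10, 8, 15),
                       origin = c(0, 0, 0))
  expect_identical(dim(st15$voxels)[3], 151L)

  expect_error(render_stack(tr, sp, bg_level = 60, fg_level = 200, mask = empty),
               "fg_level")

  # determinism with noise
  tr2 <- separated_phantom()
  m2 <- voxelize_truth(tr2, sp, extent = c(16, 16, 15), origin = c(0, 0, 0))
  a <- render_stack(tr2, sp, noise_sd = 10, speckle_density = 0.05, seed = 5, mask = m2)
  b <- render_stack(tr2, sp, noise_sd = 10, speckle_density = 0.05, seed = 5, mask = m2)
  expect_identical(a$voxels, b$voxels)

  # coarse spacing vs neck diameter -> warning channel
  expect_warning(
    render_stack(tr2, voxel_spacing(0.4), seed = 1, extent = c(16, 16, 15),
                 origin = c(0, 0, 0)),
    "coarser"
  )
})

test_that("zero blur and noise make the dark voxel set equal the truth mask", {
  fx <- standard_fixture("noiseless")
  expect_identical(nrow(fx$truth$spines), 60L)
  expect_equal(fx$truth$density_per_um, 0.8, tolerance = 0.01)
  expect_identical(dim(fx$stack$voxels), c(128L, 128L, 151L))
  mid <- (fx$stack$meta$bg_level + fx$stack$meta$fg_level) / 2
  dark <- fx$stack$voxels < mid
  expect_identical(array(dark, dim(dark)), fx$mask$mask)
})
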