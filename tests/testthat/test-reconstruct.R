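test_that("outlier removal replaces isolated impulses and nothing else", {
  sp <- voxel_spacing(0.1)
  v <- array(10, c(8, 8, 4))
  v[4, 4, 2] <- 255
  st <- image_stack(v, sp, depth = "uint8")
  out <- remove_outliers(st, 3, 4)
  expect_equal(out$voxels[4, 4, 2], 10)
  expect_true(all(out$voxels == 10))

  const <- image_stack(array(42, c(6, 6, 3)), sp, depth = "uint8")
  expect_identical(remove_outliers(const, 3, 4)$voxels, const$voxels)

  rnd <- random_stack(c(10, 10, 4), seed = 21)
  expect_identical(remove_outliers(rnd, 3, Inf)$voxels, rnd$voxels)

  expect_error(remove_outliers(image_stack(matrix(1, 2, 2), sp, depth = "uint8"),
                               window = 5), "window")
})

test_that("edge enhancement keeps constants, respects passthrough, and brackets a step", {
  sp <- voxel_spacing(0.1)
  const <- image_stack(array(0.4, c(8, 8, 4)), sp, depth = "float")
  out <- enhance_edges(const)
  expect_equal(out$voxels, const$voxels, tolerance = 1e-12)

  rnd <- image_stack(array(runif(8 * 8 * 4), c(8, 8, 4)), sp, depth = "float")
  pass <- enhance_edges(rnd, unsharp_amount = 0, edge_aware_sigma_r = Inf)
  expect_equal(pass$voxels, rnd$voxels, tolerance = 1e-12)

  # 1D step 0.2 -> 0.8 along x: unsharp overshoot brackets the step and the
  # edge location (argmax gradient) is unchanged
  v <- array(0.2, c(3, 40, 3))
  v[, 21:40, ] <- 0.8
  st <- image_stack(v, sp, depth = "float")
  enh <- enhance_edges(st, unsharp_amount = 1, unsharp_sigma = 0.2,
                       edge_aware_sigma_r = Inf)
  prof_in <- v[2, , 2]
  prof_out <- enh$voxels[2, , 2]
  expect_equal(which.max(diff(prof_out)), which.max(diff(prof_in)))
  expect_lt(prof_out[19], 0.2 - 1e-6)   # undershoot below the low plateau
  expect_gt(prof_out[22], 0.8 + 1e-6)   # overshoot above the high plateau
})

test_that("adaptive binarisation matches the brute-force local-mean oracle", {
  sp <- voxel_spacing(0.1)
  const <- image_stack(array(120, c(9, 9, 2)), sp, depth = "uint8")
  expect_false(any(binarize_adaptive(const, 5, 5 / 255)$mask))

  # bright field with a dark disk
  v <- array(200, c(41, 41, 1))
  for (i in 1:41) for (j in 1:41) {
    if ((i - 21)^2 + (j - 21)^2 <= 36) v[i, j, 1] <- 50
  }
  st <- image_stack(v, sp, depth = "uint8")
  got <- binarize_adaptive(st, 31, 10 / 255)$mask[, , 1]
  want <- oracle_adaptive_threshold(v[, , 1] / 255, 31, 10 / 255)
  expect_identical(unname(got), unname(want))
  # with a large block the mask equals the disk exactly
  disk <- v[, , 1] == 50
  expect_identical(unname(got), unname(disk))

  # polarity symmetry: binarize(invert(x), bright) == binarize(x, dark)
  rnd <- random_stack(c(16, 16, 3), seed = 31)
  dark <- binarize_adaptive(rnd, 7, 4 / 255, "dark_foreground")$mask
  bright <- binarize_adaptive(invert_luminosity(rnd), 7, 4 / 255, "bright_foreground")$mask
  expect_identical(dark, bright)
})

test_that("pruning keeps large or attached components only, and never adds voxels", {
  sp <- voxel_spacing(0.1)
  d <- c(20, 40, 10)
  m <- array(FALSE, d)
  m[5:14, 2:11, 2:6] <- TRUE                  # 500-voxel component
  m[18, 38:39, 8] <- TRUE                     # far 2-voxel speck
  m[3:4, 30, 3] <- TRUE                       # far 2-voxel speck
  vol <- binary_volume(m, sp)
  out <- prune_false_positives(vol, min_object_voxels = 10, attach_radius = 0.3)
  expect_true(all(out$mask[5:14, 2:11, 2:6]))
  expect_false(any(out$mask & !m))            # output subset of input
  expect_identical(sum(out$mask), 500L)

  # a small blob 0.2 um away from the main component is kept at 0.5 um reach
  m2 <- m
  m2[5:7, 14, 3] <- TRUE                      # 3 voxels, 2 voxels (0.2 um) from main
  out2 <- prune_false_positives(binary_volume(m2, sp), 10, 0.5)
  expect_true(all(out2$mask[5:7, 14, 3]))

  # identity configuration
  out3 <- prune_false_positives(vol, min_object_voxels = 1, attach_radius = 0)
  expect_identical(out3$mask, vol$mask)

  expect_warning(prune_false_positives(binary_volume(array(FALSE, c(4, 4, 2)), sp), 5, 1),
                 "empty")
})

test_that("per-slice flood fill closes rings, keeps open curves, and is idempotent", {
  sp <- voxel_spacing(0.1)
  ring <- array(FALSE, c(15, 15, 1))
  for (i in 1:15) for (j in 1:15) {
    r2 <- (i - 8)^2 + (j - 8)^2
    if (r2 >= 16 && r2 <= 25) ring[i, j, 1] <- TRUE
  }
  filled <- flood_fill_slices(binary_volume(ring, sp))
  disk_sel <- (row(matrix(0, 15, 15)) - 8)^2 + (col(matrix(0, 15, 15)) - 8)^2 <= 25
  expect_true(all(filled$mask[, , 1][disk_sel]))
  expect_identical(flood_fill_slices(filled)$mask, filled$mask)   # idempotent

  # C-shaped open curve stays unfilled (border-connectivity oracle)
  cshape <- array(FALSE, c(15, 15, 1))
  cshape[4:12, 4, 1] <- TRUE
  cshape[4, 4:12, 1] <- TRUE
  cshape[12, 4:12, 1] <- TRUE
  outc <- flood_fill_slices(binary_volume(cshape, sp))
  expect_identical(outc$mask, cshape)
  expect_identical(outc$mask[, , 1], oracle_fill_slice(cshape[, , 1]))
})

test_that("binarize and fill agree with reference implementations on random volumes", {
  sp <- voxel_spacing(0.1)
  for (seed in 1:8) {
    st <- random_stack(c(14, 14, 3), seed = seed)
    got <- binarize_adaptive(st, 5, 6 / 255)$mask
    for (k in 1:3) {
      expect_identical(unname(got[, , k]),
                       unname(oracle_adaptive_threshold(st$voxels[, , k] / 255, 5, 6 / 255)))
    }
    m <- withr::with_seed(seed, array(runif(14 * 14 * 3) < 0.35, c(14, 14, 3)))
    vol <- binary_volume(m, sp)
    filled <- flood_fill_slices(vol)
    for (k in 1:3) {
      expect_identical(unname(filled$mask[, , k]), unname(oracle_fill_slice(m[, , k])))
    }
    # anti-extension / extension
    expect_true(all(filled$mask | !m))                       # fill is a superset
    pr <- prune_false_positives(vol, 5, 0.2)
    expect_true(all(m | !pr$mask))                           # prune is a subset
    # shape conservation
    expect_identical(dim(filled$mask), dim(m))
    expect_identical(dim(pr$mask), dim(m))
  }
})

test_that("flood fill agrees with EBImage's fillHull as an independent cross-check", {
  skip_if_not_installed("EBImage")
  m <- withr::with_seed(77, array(runif(20 * 20 * 4) < 0.4, c(20, 20, 4)))
  got <- flood_fill_slices(binary_volume(m, voxel_spacing(0.1)))$mask
  for (k in 1:4) {
    ref <- EBImage::fillHull(EBImage::Image(m[, , k] * 1)) > 0.5
    expect_identical(unname(got[, , k]), unname(ref@.Data))
  }
})

test_that("z interpolation preserves samples, upsamples counts, and beats duplication", {
  sp <- voxel_spacing(0.1, 0.1, 0.5)
  m <- withr::with_seed(5, array(runif(9 * 9 * 11) < 0.4, c(9, 9, 11)))
  vol <- binary_volume(m, sp)
  expect_identical(interpolate_z(vol, 1)$mask, vol$mask)

  up <- interpolate_z(vol, 2)
  expect_identical(dim(up$mask)[3], 21L)
  expect_equal(up$spacing[["dz"]], 0.25)
  for (i in 1:11) expect_identical(up$mask[, , 2 * i - 1], vol$mask[, , i])

  few <- binary_volume(m[, , 1:3], sp)
  expect_warning(interpolate_z(few, 2), "linear")

  # cylinder sampled at dz = 5*dx: the interpolated volume stays within 5%
  # of the analytic capsule volume, and the upsampled mask overlaps the
  # analytic fine-grid voxelization closely
  p1 <- c(1, 4, 4.17); p2 <- c(9, 4, 4.17); r <- 1.2
  coarse <- oracle_capsule_mask(p1, p2, r, sp, c(10, 8, 8))
  vol_c <- binary_volume(coarse, sp)
  up5 <- interpolate_z(vol_c, 5)
  fine_sp <- voxel_spacing(0.1, 0.1, 0.1)
  fine <- oracle_capsule_mask(p1, p2, r, fine_sp, c(10, 8, 8))
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(jac(up5$mask, fine), 0.85)
  vol_analytic <- pi * r^2 * 8 + 4 / 3 * pi * r^3
  expect_lt(abs(sum(up5$mask) * prod(up5$spacing) - vol_analytic) / vol_analytic, 0.05)
})

test_that("the orchestrated pipeline records provenance and handles empty input", {
  sp <- voxel_spacing(0.1)
  blank <- image_stack(array(200, c(24, 24, 8)), sp, depth = "uint8")
  expect_warning(vol <- reconstruct_spines(blank, pipeline_config(zfactor = 1)),
                 "empty")
  expect_false(any(vol$mask))
  stages <- vapply(vol$provenance, `[[`, "", "stage")
  expect_identical(stages, c("remove_outliers", "enhance_edges", "binarize_adaptive",
                             "prune_false_positives", "flood_fill_slices",
                             "interpolate_z"))
  expect_true(!is.null(attr(vol, "summary")))
})
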