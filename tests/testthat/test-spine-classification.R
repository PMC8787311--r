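test_that("shaft axis of a straight cylinder tracks the true centerline and radius", {
  sp <- voxel_spacing(0.1)
  seg <- straight_segment(10, radius = 0.5, n = 21, origin = c(1.5, 4, 4))
  tr <- bare_truth(seg)
  mask <- voxelize_truth(tr, sp, extent = c(13, 8, 8), origin = c(0, 0, 0))
  axis <- extract_shaft_axis(mask)
  interior <- axis$arclen > 1 & axis$arclen < max(axis$arclen) - 1
  expect_true(all(abs(axis$y[interior] - 4) <= 0.1 + 1e-9))
  expect_true(all(abs(axis$z[interior] - 4) <= 0.1 + 1e-9))
  expect_true(all(abs(axis$radius[interior] - 0.5) <= 0.1 + 1e-9))
  expect_gt(max(axis$arclen), 8)

  # a sphere is not elongated
  ball <- neuron_morphology(data.frame(id = 1, type = 1, x = 4, y = 4, z = 4,
                                       radius = 2, parent = -1))
  bmask <- voxelize_truth(bare_truth(ball), sp, extent = c(8, 8, 8), origin = c(0, 0, 0))
  expect_error(extract_shaft_axis(bmask), "elongated")
  expect_error(extract_shaft_axis(binary_volume(array(FALSE, c(5, 5, 5)), sp)),
               "foreground")
})

test_that("segmentation finds well-separated spines at their arclength positions", {
  sp <- voxel_spacing(0.1)
  tr <- separated_phantom(seed = 42, n_spines = 3)
  mask <- voxelize_truth(tr, sp, extent = c(16, 16, 15), origin = c(0, 0, 0))
  axis <- extract_shaft_axis(mask)
  cands <- segment_spines(mask, axis)
  expect_length(cands, 3L)
  att <- do.call(rbind, lapply(cands, function(c) c$attachment))
  truth_att <- as.matrix(tr$spines[, c("attach_x", "attach_y", "attach_z")])
  for (i in seq_len(3)) {
    d <- sqrt(rowSums(sweep(truth_att, 2, att[i, ])^2))
    expect_lt(min(d), 0.25)      # within ~2 voxels of a true attachment
  }

  # bare shaft -> no spine records
  bare <- voxelize_truth(bare_truth(straight_segment(10)), sp,
                         extent = c(12, 8, 8), origin = c(0, 0, 0))
  expect_length(segment_spines(bare, extract_shaft_axis(bare)), 0L)
})

test_that("measured features recover generator geometry on clean single spines", {
  sp <- voxel_spacing(0.1)
  seg <- straight_segment(8, radius = 0.35, n = 17, origin = c(1, 4, 7.5))
  one_spine <- function(class_label, seed) {
    decorate_with_spines(seg, 0.2, class_mix = setNames(1, class_label),
                         seed = seed, n_spines = 1L)
  }
  run_one <- function(tr) {
    mask <- voxelize_truth(tr, sp, extent = c(10, 8, 15), origin = c(0, 0, 0))
    classify_spines(mask)
  }

  mush <- one_spine("mushroom", 3)
  fm <- run_one(mush)
  expect_identical(nrow(fm), 1L)
  expect_true(fm$neck_present)
  expect_lt(abs(fm$head_diameter - mush$spines$head_diameter), 0.12)
  expect_lt(abs(fm$neck_diameter - mush$spines$neck_diameter), 0.12)
  expect_identical(fm$class, "mushroom")

  # hemispherical bump: no constriction, no neck
  stub <- one_spine("stubby", 5)
  fs <- run_one(stub)
  expect_false(fs$neck_present)

  # double-headed spine: two protrusions
  ram <- one_spine("ramified", 8)
  fr <- run_one(ram)
  expect_identical(fr$n_protrusions, 2L)
  expect_identical(fr$class, "ramified")

  expect_error(measure_spine(array(FALSE, c(3, 3, 3)), c(1, 1, 1), sp),
               "2 voxels")
})

test_that("the rule table classifies by priority and always returns one label", {
  base <- tibble::tibble(
    neck_present = TRUE, neck_length = 0.5, neck_diameter = 0.15,
    head_diameter = 0.6, base_diameter = 0.3, n_protrusions = 1L,
    head_shape = 0.8, protrusion_length = 1.1, spinule_count = 0L
  )
  # ramified beats everything
  expect_identical(classify_spine(transform(base, n_protrusions = 2L)), "ramified")
  expect_identical(classify_spine(transform(base, n_protrusions = 3L,
                                            neck_present = FALSE)), "ramified")
  # head 0.6 / neck 0.15 -> mushroom (independent rule-table evaluation:
  # ratio 4 >= 1.5 and outside the 10% band)
  expect_identical(classify_spine(base), "mushroom")
  # thin: necked, modest head, elongated
  expect_identical(
    classify_spine(transform(base, head_diameter = 0.19, neck_diameter = 0.15,
                             protrusion_length = 1.0)),
    "thin"
  )
  # neckless: stubby vs wide vs filopodial vs atypical
  neckless <- transform(base, neck_present = FALSE)
  expect_identical(classify_spine(transform(neckless, protrusion_length = 0.33,
                                            base_diameter = 0.42)), "stubby")
  expect_identical(classify_spine(transform(neckless, protrusion_length = 0.3,
                                            base_diameter = 0.6)), "wide")
  expect_identical(classify_spine(transform(neckless, protrusion_length = 1.2,
                                            base_diameter = 0.3,
                                            neck_diameter = 0.2)), "thin")
  expect_identical(classify_spine(transform(neckless, protrusion_length = 0.5,
                                            base_diameter = 0.28,
                                            neck_diameter = 0.25)), "atypical")
  # boundary band -> transitional
  expect_identical(
    classify_spine(transform(base, head_diameter = 0.15 * 1.5)), "transitional")

  # totality and uniqueness over random feature vectors
  labs <- withr::with_seed(1, {
    vapply(1:200, function(i) {
      f <- tibble::tibble(
        neck_present = runif(1) < 0.5, neck_length = runif(1, 0, 1),
        neck_diameter = runif(1, 0.05, 0.6), head_diameter = runif(1, 0.05, 1),
        base_diameter = runif(1, 0.05, 1.2), n_protrusions = sample(1:3, 1),
        head_shape = runif(1), protrusion_length = runif(1, 0.1, 2),
        spinule_count = 0L
      )
      classify_spine(f)
    }, "")
  })
  expect_true(all(labs %in% c("thin", "stubby", "wide", "mushroom", "ramified",
                              "transitional", "atypical")))
})

test_that("classification is scale-equivariant and rotation-robust", {
  # scaling geometry and spacing together leaves every label unchanged
  sp <- voxel_spacing(0.1)
  tr <- separated_phantom()
  mask <- voxelize_truth(tr, sp, extent = c(16, 16, 15), origin = c(0, 0, 0))
  s1 <- classify_spines(mask)
  mask2 <- binary_volume(mask$mask, voxel_spacing(0.2))   # same grid, x2 units
  s2 <- classify_spines(mask2)
  expect_identical(s1$class, s2$class)
  expect_equal(s2$protrusion_length, 2 * s1$protrusion_length, tolerance = 1e-9)

  # rotating the phantom 90 degrees about z changes no class labels
  st <- render_stack(tr, sp, psf_sigma_xy = 0, psf_sigma_z = 0, seed = 3, mask = mask)
  vol <- reconstruct_spines(st, pipeline_config(zfactor = 1))
  a <- classify_spines(vol)
  rotm <- aperm(vol$mask, c(2, 1, 3))[, dim(vol$mask)[1]:1, , drop = FALSE]
  b <- classify_spines(binary_volume(rotm, sp))
  expect_identical(sort(a$class), sort(b$class))
})

test_that("spine density reports counts per micron with qualitative bands", {
  recs <- tibble::tibble(spine_id = 1:10, class = rep("thin", 10))
  dens <- spine_density(recs, decorated_length = 20)
  expect_equal(dens$density_per_um, 0.5)
  expect_identical(dens$band, "moderate")

  none <- spine_density(recs[0, ], decorated_length = 20)
  expect_equal(none$density_per_um, 0)
  expect_identical(none$band, "sparse")

  expect_error(spine_density(recs, decorated_length = 0), "positive")
})
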