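test_that("TIFF write/read round-trips 8-bit stacks voxel-identically", {
  st <- random_stack(c(8, 8, 4), seed = 11)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(dim(back$voxels), dim(st$voxels))
  expect_true(all(back$voxels == st$voxels))
  expect_equal(unclass(back$spacing), unclass(st$spacing))

  one <- image_stack(matrix(7, 5, 6), voxel_spacing(0.2), depth = "uint8")
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_stack(one, p1)
  r1 <- read_stack(p1)
  expect_equal(dim(r1$voxels)[3], 1L)
  expect_true(all(r1$voxels == 7))
})

test_that("invalid stacks are rejected at construction and read", {
  expect_error(image_stack(array(0, c(4, 4, 0)), voxel_spacing(0.1)), "slice")
  expect_error(image_stack(array(300, c(2, 2, 1)), voxel_spacing(0.1), "uint8"),
               "range")
  expect_error(voxel_spacing(0), "positive")
  # mixed page sizes: write two different-size pages manually
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.5, 6, 6)), p,
                  bits.per.sample = 8L)
  expect_error(read_stack(p, voxel_spacing(0.1)), "inconsistent")
})

test_that("float stacks need an explicit quantization flag to be written", {
  fl <- image_stack(array(runif(64), c(4, 4, 4)), voxel_spacing(0.1), depth = "float")
  p <- withr::local_tempfile(fileext = ".tif")
  expect_error(write_stack(fl, p), "quantize")
  write_stack(fl, p, quantize = TRUE)
  back <- read_stack(p)
  expect_equal(back$depth, "uint8")
  expect_true(max(abs(back$voxels - round(fl$voxels * 255))) == 0)
})

test_that("to_monochrome8 collapses RGB with ITU-R 601 weights and rescales depth", {
  rgb <- image_stack(array(200, c(3, 3, 2, 3)), voxel_spacing(0.1), depth = "uint8")
  mono <- to_monochrome8(rgb)
  expect_equal(length(dim(mono$voxels)), 3L)
  expect_true(all(mono$voxels == 200))

  mixed <- array(0, c(1, 1, 1, 3))
  mixed[1, 1, 1, ] <- c(255, 0, 0)
  red <- to_monochrome8(image_stack(mixed, voxel_spacing(0.1), depth = "uint8"))
  expect_equal(as.numeric(red$voxels), round(0.299 * 255))

  u16 <- image_stack(array(65535, c(2, 2, 1)), voxel_spacing(0.1), depth = "uint16")
  expect_true(all(to_monochrome8(u16)$voxels == 255))

  g8 <- random_stack(seed = 3)
  expect_identical(to_monochrome8(g8), g8)      # idempotent on 8-bit grayscale
})

test_that("invert_luminosity is an involution that preserves spacing and shape", {
  st <- random_stack(c(6, 7, 3), seed = 5)
  inv <- invert_luminosity(st)
  expect_true(all(inv$voxels == 255 - st$voxels))
  expect_identical(invert_luminosity(inv)$voxels, st$voxels)
  expect_equal(unclass(inv$spacing), unclass(st$spacing))
  const <- image_stack(array(100, c(2, 2, 2)), voxel_spacing(0.1), depth = "uint8")
  expect_true(all(invert_luminosity(const)$voxels == 155))
  fl <- image_stack(array(0.5, c(2, 2, 1)), voxel_spacing(0.1), depth = "float")
  expect_error(invert_luminosity(fl), "8-bit")
})

test_that("composite projection has min semantics and the declared invariances", {
  st <- random_stack(c(6, 6, 5), seed = 9)
  proj <- composite_projection(st)
  expect_equal(dim(proj), dim(st$voxels)[1:2])

  # single slice -> identity
  one <- image_stack(st$voxels[, , 1, drop = FALSE], st$spacing, depth = "uint8")
  expect_equal(unname(composite_projection(one)[, ]), unname(st$voxels[, , 1]))

  # a dark line on one slice survives
  v <- array(255, c(5, 5, 2))
  v[3, , 2] <- 0
  dark <- composite_projection(image_stack(v, voxel_spacing(0.1), depth = "uint8"))
  expect_true(all(dark[3, ] == 0) && all(dark[-3, ] == 255))

  # dark-pixel set equals union of per-slice dark sets (brute-force oracle)
  fx <- fixture_run("noiseless")
  sub <- image_stack(fx$fx$stack$voxels[, , seq(20, 40)], fx$fx$spacing, depth = "uint8")
  p <- composite_projection(sub)
  dark_union <- Reduce(`|`, lapply(seq_len(dim(sub$voxels)[3]),
                                   function(i) sub$voxels[, , i] < 130))
  expect_identical(unname(p < 130), unname(dark_union))

  # idempotent under slice duplication
  dup <- image_stack(st$voxels[, , rep(seq_len(5), each = 2)], st$spacing, depth = "uint8")
  expect_identical(composite_projection(dup), composite_projection(st))
  expect_identical(composite_projection(dup, "mean"), composite_projection(st, "mean"))
})
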