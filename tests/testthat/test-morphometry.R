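test_that("SWC reading validates tree invariants with distinct errors", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# test cell",
               "1 1 0 0 0 5 -1",
               "2 3 0 10 0 1 1",
               "3 3 0 20 0 0.8 2"), p)
  m <- read_swc(p)
  expect_identical(nrow(m), 3L)
  expect_identical(m$id[m$parent == -1L], 1L)

  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 1 0 1 9"), bad)
  expect_error(read_swc(bad), "dangling")
  writeLines(c("1 1 0 0 0 5 -1", "1 3 0 1 0 1 1"), bad)
  expect_error(read_swc(bad), "duplicate")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 1 0 0 1"), bad)
  expect_error(read_swc(bad), "positive")
  writeLines(c("1 3 0 0 0 1 2", "2 3 0 1 0 1 1"), bad)
  expect_error(read_swc(bad), "root")

  # round trip of generator output is node-for-node equal
  g <- generate_spindle_swc(spindle_params(seed = 12))
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(g, f)
  back <- read_swc(f)
  expect_equal(as.data.frame(back), as.data.frame(g), tolerance = 1e-6)
})

test_that("soma and dendrite metrics reproduce closed forms", {
  # spherical soma
  ball <- neuron_morphology(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                                       radius = 3, parent = -1))
  sb <- soma_metrics(ball)
  expect_equal(sb$soma_length, 6)
  expect_equal(sb$soma_max_diameter, 6)
  expect_equal(sb$soma_volume, 4 / 3 * pi * 27)

  # straight cylinder edge: h = 10, r = 1 -> volume 10*pi
  cyl <- neuron_morphology(data.frame(id = 1:2, type = 3, x = c(0, 10), y = 0,
                                      z = 0, radius = 1, parent = c(-1, 1)))
  dm <- dendrite_metrics(cyl)
  expect_equal(dm$total_length, 10)
  expect_equal(dm$total_volume, 10 * pi)
  expect_identical(dm$n_branches, 1L)

  # frustum r1 = 1, r2 = 2, h = 3 -> 7*pi
  fr <- neuron_morphology(data.frame(id = 1:2, type = 3, x = c(0, 3), y = 0,
                                     z = 0, radius = c(1, 2), parent = c(-1, 1)))
  expect_equal(dendrite_metrics(fr)$total_volume, 7 * pi)

  # Y-tree: one primary splitting once -> 3 segments
  y <- neuron_morphology(data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 0, 0, 3, -3), y = c(0, 2, 6, 9, 9), z = 0,
    radius = c(4, 1, 1, 0.5, 0.5), parent = c(-1, 1, 2, 3, 3)
  ))
  expect_identical(dendrite_metrics(y)$n_branches, 3L)
  expect_error(soma_metrics(cyl), "soma")
  expect_error(dendrite_metrics(ball), "dendritic")
})

test_that("metrics match the brute-force per-edge oracle on random trees", {
  for (s in 1:50) {
    m <- generate_spindle_swc(spindle_params(
      branch_profile = if (s %% 2) "profuse" else "sparse",
      total_extent = 80 + 5 * (s %% 7), seed = s
    ))
    expect_lte(nrow(m), 400)
    dm <- dendrite_metrics(m)
    orc <- oracle_dendrite_metrics(m)
    expect_identical(dm$n_branches, as.integer(orc$n_branches))
    expect_lt(abs(dm$total_length - orc$total_length) / orc$total_length, 1e-9)
    expect_lt(abs(dm$total_volume - orc$total_volume) / orc$total_volume, 1e-9)
  }
})

test_that("metrics are rigid-motion invariant, scale correctly, and are additive", {
  m <- generate_spindle_swc(spindle_params(branch_profile = "profuse", seed = 23))
  d0 <- dendrite_metrics(m)
  R <- rotation_matrix("z", 37) %*% rotation_matrix("x", -14)
  mr <- transform_morphology(m, R, translate = c(11, -4, 2))
  dr <- dendrite_metrics(mr)
  expect_lt(abs(dr$total_length - d0$total_length) / d0$total_length, 1e-9)
  expect_lt(abs(dr$total_volume - d0$total_volume) / d0$total_volume, 1e-9)
  expect_identical(dr$n_branches, d0$n_branches)
  sr <- soma_metrics(mr)
  s0 <- soma_metrics(m)
  expect_equal(sr$soma_volume, s0$soma_volume, tolerance = 1e-9)

  ms <- transform_morphology(m, scale = 3)
  ds <- dendrite_metrics(ms)
  expect_equal(ds$total_length, 3 * d0$total_length, tolerance = 1e-9)
  expect_equal(ds$total_volume, 27 * d0$total_volume, tolerance = 1e-9)

  # additivity over the per-primary breakdown
  expect_equal(sum(d0$per_primary$length), d0$total_length)
  expect_equal(sum(d0$per_primary$volume), d0$total_volume)
  expect_identical(sum(d0$per_primary$n_branches), d0$n_branches)
})

test_that("the spindle qualifier accepts the spindle fixture and rejects controls", {
  m <- generate_spindle_swc(spindle_params(37, 19, seed = 2))
  q <- classify_spindle(m)
  expect_true(q$is_spindle)
  expect_true(all(q$criteria$pass))

  pyr <- generate_spindle_swc(spindle_params(37, 19, n_primary = 6, seed = 3))
  qp <- classify_spindle(pyr)
  expect_false(qp$is_spindle)
  expect_false(qp$criteria$pass[qp$criteria$criterion == "two_primary_dendrites"])

  tilted <- transform_morphology(m, rotation_matrix("z", 60))
  qt <- classify_spindle(tilted)
  expect_false(qt$is_spindle)
  expect_false(qt$criteria$pass[qt$criteria$criterion == "vertical_orientation"])

  # tidy/glance accessors
  expect_identical(nrow(tidy(q)), 4L)
  expect_true(glance(q)$is_spindle)
  rep <- morphometry_report(m)
  expect_s3_class(rep, "morphometry_report")
  expect_identical(nrow(tidy(rep)), ncol(rep))
})
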