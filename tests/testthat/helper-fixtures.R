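# Shared fixtures. The full-stack pipeline runs are expensive (tens of
# seconds), so they are computed once per test session and shared across
# test files through this cache.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# full reconstruction + classification of a standard-fixture variant
fixture_run <- function(variant = "noiseless") {
  cached(paste0("run_", variant), {
    fx <- standard_fixture(variant)
    vol <- reconstruct_spines(fx$stack, fx$config)
    axis <- extract_shaft_axis(vol)
    spines <- classify_spines(vol, axis)
    ev <- match_spines(spines, fx$truth)
    list(fx = fx, vol = vol, axis = axis, spines = spines, ev = ev)
  })
}

# a small straight-dendrite phantom with a handful of well-separated spines;
# used for invariance checks where boundary chatter must not matter
separated_phantom <- function(seed = 42, n_spines = 6) {
  n <- 41
  m <- neuron_morphology(data.frame(
    id = seq_len(n), type = 3L,
    x = seq(1.5, 14.5, length.out = n), y = 8, z = 7.5,
    radius = 0.35, parent = c(-1L, seq_len(n - 1))
  ))
  decorate_with_spines(m, density_per_um = 0.45, grouping = 0, seed = seed,
                       n_spines = n_spines, min_separation = 1.6)
}

# straight dendritic segment morphology (single unbranched path)
straight_segment <- function(length_um = 10, radius = 0.4, n = 21,
                             origin = c(1, 4, 4)) {
  neuron_morphology(data.frame(
    id = seq_len(n), type = 3L,
    x = origin[1] + seq(0, length_um, length.out = n),
    y = origin[2], z = origin[3],
    radius = radius, parent = c(-1L, seq_len(n - 1))
  ))
}

bare_truth <- function(m) {
  decorate_with_spines(m, density_per_um = 0, seed = 1)
}

# brute-force 2D local-mean adaptive threshold (edge-replicated), the oracle
# for binarize_adaptive
oracle_adaptive_threshold <- function(img, block, offset, dark = TRUE) {
  r <- block %/% 2
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ys <- pmin(pmax(i + (-r:r), 1), ny)
    xs <- pmin(pmax(j + (-r:r), 1), nx)
    mu <- mean(img[ys, xs])
    out[i, j] <- if (dark) img[i, j] < mu - offset - 1e-9 else img[i, j] > mu + offset + 1e-9
  }
  out
}

# brute-force per-slice flood fill oracle: BFS over background from the
# border, 4-connectivity
oracle_fill_slice <- function(sl) {
  ny <- nrow(sl); nx <- ncol(sl)
  reach <- matrix(FALSE, ny, nx)
  queue <- list()
  push <- function(i, j) {
    if (i >= 1 && i <= ny && j >= 1 && j <= nx && !reach[i, j] && !sl[i, j]) {
      reach[i, j] <<- TRUE
      queue[[length(queue) + 1L]] <<- c(i, j)
    }
  }
  for (j in seq_len(nx)) { push(1, j); push(ny, j) }
  for (i in seq_len(ny)) { push(i, 1); push(i, nx) }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  sl | !reach
}

# brute-force morphometry oracle: per-edge traversal sums and a
# tips-plus-branchpoints segment count
oracle_dendrite_metrics <- function(m) {
  pidx <- match(m$parent, m$id)
  dend <- which(m$type %in% c(3L, 4L))
  len <- 0; vol <- 0
  for (i in dend) {
    p <- pidx[i]
    if (is.na(p) || !(m$type[p] %in% c(3L, 4L))) next
    h <- sqrt((m$x[i] - m$x[p])^2 + (m$y[i] - m$y[p])^2 + (m$z[i] - m$z[p])^2)
    len <- len + h
    vol <- vol + pi * h * (m$radius[i]^2 + m$radius[i] * m$radius[p] + m$radius[p]^2) / 3
  }
  nch <- integer(nrow(m))
  for (i in dend) {
    p <- pidx[i]
    if (!is.na(p) && m$type[p] %in% c(3L, 4L)) nch[p] <- nch[p] + 1L
  }
  tips <- sum(nch[dend] == 0L)
  bps <- sum(nch[dend] >= 2L)
  list(total_length = len, total_volume = vol, n_branches = tips + bps)
}

# analytic point-in-capsule voxelization oracle
oracle_capsule_mask <- function(p1, p2, r, spacing, extent, origin = c(0, 0, 0)) {
  nx <- floor(extent[1] / spacing[["dx"]] + 1e-6) + 1L
  ny <- floor(extent[2] / spacing[["dy"]] + 1e-6) + 1L
  nz <- floor(extent[3] / spacing[["dz"]] + 1e-6) + 1L
  out <- array(FALSE, dim = c(ny, nx, nz))
  d <- p2 - p1
  len2 <- sum(d^2)
  for (k in seq_len(nz)) for (j in seq_len(nx)) for (i in seq_len(ny)) {
    p <- origin + c((j - 1) * spacing[["dx"]], (i - 1) * spacing[["dy"]],
                    (k - 1) * spacing[["dz"]])
    tt <- min(max(sum((p - p1) * d) / len2, 0), 1)
    out[i, j, k] <- sum((p - p1 - tt * d)^2) <= r^2
  }
  out
}

random_stack <- function(dims = c(8, 8, 4), seed = 1, spacing = voxel_spacing(0.1)) {
  withr::with_seed(seed, {
    image_stack(array(as.numeric(sample(0:255, prod(dims), replace = TRUE)),
                      dim = dims),
                spacing, depth = "uint8")
  })
}
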