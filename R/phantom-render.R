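# Rendering: phantom geometry -> ground-truth voxel mask -> brightfield-like
# 8-bit stack. Dark tubular structure on a bright ground, anisotropic
# Gaussian PSF, punctate dark speckle ("unspecific silver precipitate"),
# multiplicative illumination ramp, additive Gaussian noise.

voxel_grid <- function(spacing, extent, origin = c(0, 0, 0)) {
  nx <- floor(extent[1] / spacing[["dx"]] + 1e-6) + 1L
  ny <- floor(extent[2] / spacing[["dy"]] + 1e-6) + 1L
  nz <- floor(extent[3] / spacing[["dz"]] + 1e-6) + 1L
  list(
    nx = nx, ny = ny, nz = nz,
    xs = origin[1] + (seq_len(nx) - 1) * spacing[["dx"]],
    ys = origin[2] + (seq_len(ny) - 1) * spacing[["dy"]],
    zs = origin[3] + (seq_len(nz) - 1) * spacing[["dz"]]
  )
}

# primitive constructors
prim_capsule <- function(p1, p2, r1, r2 = r1) {
  list(kind = "capsule", p1 = p1, p2 = p2, r1 = r1, r2 = r2)
}
prim_sphere <- function(center, r) list(kind = "sphere", p1 = center, r1 = r)
prim_ellipsoid <- function(center, axes, semi) {
  list(kind = "ellipsoid", p1 = center, axes = axes, semi = semi)
}

prim_bbox <- function(p) {
  switch(p$kind,
    capsule = {
      r <- max(p$r1, p$r2)
      rbind(pmin(p$p1, p$p2) - r, pmax(p$p1, p$p2) + r)
    },
    sphere = rbind(p$p1 - p$r1, p$p1 + p$r1),
    ellipsoid = {
      r <- max(p$semi)
      rbind(p$p1 - r, p$p1 + r)
    }
  )
}

# geometry primitives for one spine record (a row of truth$spines)
spine_primitives <- function(row) {
  attach <- c(row$attach_x, row$attach_y, row$attach_z)
  dir <- c(row$dir_x, row$dir_y, row$dir_z)
  tang <- c(row$tan_x, row$tan_y, row$tan_z)
  g <- row$geom[[1]]
  prims <- list()
  add <- function(p) prims[[length(prims) + 1L]] <<- p
  head_center <- NULL
  base <- attach - dir * 0.05     # slight inset so the spine fuses with the shaft
  switch(row$class_label,
    thin = ,
    transitional = ,
    mushroom = {
      neck_end <- attach + dir * g$neck_length
      add(prim_capsule(base, neck_end, g$neck_diameter / 2))
      head_center <- neck_end + dir * (g$head_diameter / 2 * 0.8)
      add(prim_sphere(head_center, g$head_diameter / 2))
    },
    stubby = ,
    wide = {
      axes <- cbind(dir, orthogonal_unit(dir), unit(pracma_cross(dir, orthogonal_unit(dir))))
      add(prim_ellipsoid(attach, axes, c(g$height, g$lateral_semi, g$lateral_semi)))
      head_center <- attach + dir * (g$height / 2)
    },
    ramified = {
      stalk_end <- attach + dir * g$neck_length
      add(prim_capsule(base, stalk_end, g$neck_diameter / 2))
      sep_axis <- unit(pracma_cross(dir, tang))
      for (sgn in c(-1, 1)) {
        bd <- unit(rotate_about(dir, sep_axis, sgn * g$branch_angle))
        br_end <- stalk_end + bd * g$branch_length
        add(prim_capsule(stalk_end, br_end, g$neck_diameter / 2 * 0.9))
        add(prim_sphere(br_end + bd * (g$head_diameter / 2 * 0.8),
                        g$head_diameter / 2))
      }
      head_center <- stalk_end + dir * (g$branch_length + g$head_diameter / 2)
    },
    atypical = {
      p <- attach
      for (k in 1:2) {
        neck_end <- p + dir * g$neck_length
        add(prim_capsule(p - dir * 0.05, neck_end, g$neck_diameter / 2))
        head_center <- neck_end + dir * (g$head_diameter / 2 * 0.85)
        add(prim_sphere(head_center, g$head_diameter / 2))
        p <- head_center + dir * (g$head_diameter / 2 * 0.85)
      }
    },
    stop("unknown class in truth table: ", row$class_label)
  )
  if (isTRUE(row$has_spinule) && !is.null(head_center)) {
    tip <- head_center + dir * (row$head_diameter / 2)
    add(prim_capsule(tip, tip + dir * row$spinule_length, 0.08))
  }
  prims
}

truth_primitives <- function(truth) {
  m <- truth$morphology
  prims <- list()
  add <- function(p) prims[[length(prims) + 1L]] <<- p
  soma <- soma_rows(m)
  if (length(soma) >= 3L) {
    xyz <- as.matrix(m[soma, c("x", "y", "z")])
    pc <- prcomp(xyz, center = TRUE)
    ctr <- colMeans(xyz)
    L <- diff(range(xyz %*% pc$rotation[, 1]))
    D <- 2 * max(m$radius[soma])
    ax1 <- pc$rotation[, 1]
    ax2 <- orthogonal_unit(ax1)
    add(prim_ellipsoid(ctr, cbind(ax1, ax2, unit(pracma_cross(ax1, ax2))),
                       c(L / 2, D / 2, D / 2)))
  } else if (length(soma) > 0L) {
    for (s in soma) add(prim_sphere(unlist(m[s, c("x", "y", "z")]), m$radius[s]))
  }
  pidx <- match(m$parent, m$id)
  for (i in seq_len(nrow(m))) {
    p <- pidx[i]
    if (is.na(p)) next
    if (!(m$type[i] %in% c(2L, 3L, 4L)) || !(m$type[p] %in% c(2L, 3L, 4L))) next
    add(prim_capsule(c(m$x[p], m$y[p], m$z[p]), c(m$x[i], m$y[i], m$z[i]),
                     m$radius[p], m$radius[i]))
  }
  if (nrow(truth$spines)) {
    for (i in seq_len(nrow(truth$spines))) {
      for (pr in spine_primitives(truth$spines[i, ])) add(pr)
    }
  }
  prims
}

# paint a primitive into a logical mask (voxel-centre point-inclusion test)
paint_primitive <- function(mask, grid, prim) {
  bb <- prim_bbox(prim)
  xi <- which(grid$xs >= bb[1, 1] & grid$xs <= bb[2, 1])
  yi <- which(grid$ys >= bb[1, 2] & grid$ys <= bb[2, 2])
  zi <- which(grid$zs >= bb[1, 3] & grid$zs <= bb[2, 3])
  if (!length(xi) || !length(yi) || !length(zi)) return(mask)
  px <- grid$xs[xi]; py <- grid$ys[yi]; pz <- grid$zs[zi]
  ny_ <- length(yi); nx_ <- length(xi); nz_ <- length(zi)
  P <- cbind(
    rep(px, each = ny_, times = nz_),
    rep(py, times = nx_ * nz_),
    rep(pz, each = ny_ * nx_)
  )
  inside <- switch(prim$kind,
    capsule = {
      d <- prim$p2 - prim$p1
      len2 <- sum(d^2)
      rel <- sweep(P, 2, prim$p1)
      tt <- if (len2 > 0) clamp(as.vector(rel %*% d) / len2, 0, 1) else 0
      closest <- outer(tt, d)
      rr <- prim$r1 + (prim$r2 - prim$r1) * tt
      rowSums((rel - closest)^2) <= rr^2
    },
    sphere = {
      rel <- sweep(P, 2, prim$p1)
      rowSums(rel^2) <= prim$r1^2
    },
    ellipsoid = {
      rel <- sweep(P, 2, prim$p1) %*% prim$axes
      rowSums(sweep(rel, 2, prim$semi, `/`)^2) <= 1
    }
  )
  if (any(inside)) {
    sub <- mask[yi, xi, zi]
    sub[inside] <- TRUE
    mask[yi, xi, zi] <- sub
  }
  mask
}

#' Voxelize phantom ground truth into a binary mask
#'
#' Voxel centres inside any geometric primitive (soma ellipsoid, dendritic
#' frusta, spine necks/heads, spinules) are foreground. This mask is the
#' ground truth against which reconstructions are scored.
#'
#' @param truth a `phantom_truth` from [decorate_with_spines()].
#' @param spacing a [voxel_spacing()].
#' @param extent physical extents (ex, ey, ez) in um; slice count is
#'   `floor(ez / dz) + 1` (voxel-centre convention). Default: geometry
#'   bounding box plus a margin.
#' @param origin physical coordinate of voxel (1, 1, 1)'s centre.
#' @return A [binary_volume()].
#' @export
voxelize_truth <- function(truth, spacing, extent = NULL, origin = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  prims <- truth_primitives(truth)
  if (is.null(extent) || is.null(origin)) {
    bbs <- lapply(prims, prim_bbox)
    lo <- Reduce(pmin, lapply(bbs, function(b) b[1, ])) - 1
    hi <- Reduce(pmax, lapply(bbs, function(b) b[2, ])) + 1
    origin <- origin %||% lo
    extent <- extent %||% (hi - lo)
  }
  grid <- voxel_grid(spacing, extent, origin)
  mask <- array(FALSE, dim = c(grid$ny, grid$nx, grid$nz))
  for (p in prims) mask <- paint_primitive(mask, grid, p)
  binary_volume(mask, spacing, provenance = list(list(stage = "voxelize_truth",
                                                      params = list(origin = origin, extent = extent))))
}

# separable Gaussian blur with edge replication; sigma in voxels per axis
blur_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (is.na(s) || s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    n <- d[ax]
    out <- array(0, dim = d)
    for (k in seq(-r, r)) {
      idx <- clamp(seq_len(n) + k, 1L, n)
      shifted <- switch(ax,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE]
      )
      out <- out + w[k + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

#' Render a phantom as a brightfield-like 8-bit stack
#'
#' Voxelizes the phantom geometry, blurs it with an anisotropic Gaussian PSF
#' (axial sigma larger than lateral, mimicking brightfield axial elongation),
#' adds punctate dark speckle, a multiplicative illumination ramp along x and
#' additive Gaussian noise, then quantizes to 8-bit. Foreground must be
#' darker than background (dark structure, bright ground). Deterministic for
#' a fixed seed.
#'
#' @inheritParams voxelize_truth
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, um (0 disables blur).
#' @param bg_level,fg_level background/foreground intensities (0..255,
#'   `fg_level < bg_level`).
#' @param speckle_density expected speckles per 1000 voxels.
#' @param illumination_gradient fractional intensity ramp across x.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed RNG seed for speckle and noise.
#' @param mask optional precomputed [voxelize_truth()] result on the same
#'   grid (avoids re-voxelizing).
#' @return An 8-bit [image_stack()].
#' @export
render_stack <- function(truth, spacing, psf_sigma_xy = 0.15, psf_sigma_z = 0.30,
                         bg_level = 200, fg_level = 60, speckle_density = 0,
                         illumination_gradient = 0, noise_sd = 0, seed = 1L,
                         extent = NULL, origin = NULL, mask = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (fg_level >= bg_level) stop("brightfield rendering requires fg_level < bg_level")
  if (nrow(truth$spines)) {
    min_neck <- min(truth$spines$neck_diameter)
    if (min(spacing) > min_neck) {
      warning(sprintf("voxel spacing (%.3g um) is coarser than the smallest spine neck (%.3g um)",
                      min(spacing), min_neck))
    }
  }
  if (is.null(mask)) mask <- voxelize_truth(truth, spacing, extent, origin)
  stopifnot(inherits(mask, "binary_volume"))
  field <- array(as.numeric(mask$mask), dim = dim(mask$mask))
  d <- dim(field)
  with_seed(seed, {
    n_speck <- round(speckle_density * prod(d) / 1000)
    if (n_speck > 0) {
      cy <- runif(n_speck, 1, d[1])
      cx <- runif(n_speck, 1, d[2])
      cz <- runif(n_speck, 1, d[3])
      rad <- runif(n_speck, 0.05, 0.12)
      for (i in seq_len(n_speck)) {
        ry <- ceiling(rad[i] / spacing[["dy"]]); rx <- ceiling(rad[i] / spacing[["dx"]])
        rz <- ceiling(rad[i] / spacing[["dz"]])
        yy <- clamp(round(cy[i]) + (-ry:ry), 1, d[1])
        xx <- clamp(round(cx[i]) + (-rx:rx), 1, d[2])
        zz <- clamp(round(cz[i]) + (-rz:rz), 1, d[3])
        field[yy, xx, zz] <- pmax(field[yy, xx, zz], 0.85)
      }
    }
    sig <- c(psf_sigma_xy / spacing[["dy"]], psf_sigma_xy / spacing[["dx"]],
             psf_sigma_z / spacing[["dz"]])
    if (any(sig > 0)) field <- blur_gaussian(field, sig)
    img <- bg_level - (bg_level - fg_level) * field
    if (illumination_gradient != 0) {
      ramp <- 1 + illumination_gradient * ((seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 0.5)
      img <- sweep(img, 2, ramp, `*`)
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- round(clamp(img, 0, 255))
    image_stack(img, mask$spacing, depth = "uint8",
                meta = list(bg_level = bg_level, fg_level = fg_level,
                            psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                            noise_sd = noise_sd, seed = seed))
  })
}
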