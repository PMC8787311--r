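# Separating spines from the reconstructed volume: centerline extraction of
# the dominant shaft, protrusion segmentation off the shaft envelope, and
# per-spine geometric measurement (width profile, neck/head decomposition,
# protrusion counting, spinules).

linear_index <- function(d, y, x, z) y + d[1] * ((x - 1) + d[2] * (z - 1))

index_to_coord <- function(d, idx, spacing, origin = c(0, 0, 0)) {
  z <- (idx - 1) %/% (d[1] * d[2])
  rem <- (idx - 1) %% (d[1] * d[2])
  x <- rem %/% d[1]
  y <- rem %% d[1]
  cbind(x = origin[1] + x * spacing[["dx"]],
        y = origin[2] + y * spacing[["dy"]],
        z = origin[3] + z * spacing[["dz"]])
}

# linear indices of foreground voxels with at least one 6-neighbour outside
# the mask (or on the volume boundary)
surface_voxels <- function(mask, d) {
  interior <- mask
  interior[] <- TRUE
  for (ax in 1:3) {
    n <- d[ax]
    lo <- c(1, seq_len(n - 1))
    hi <- c(seq_len(n - 1) + 1, n)
    sh_lo <- switch(ax, mask[lo, , , drop = FALSE], mask[, lo, , drop = FALSE],
                    mask[, , lo, drop = FALSE])
    sh_hi <- switch(ax, mask[hi, , , drop = FALSE], mask[, hi, , drop = FALSE],
                    mask[, , hi, drop = FALSE])
    interior <- interior & sh_lo & sh_hi
  }
  which(mask & !interior)
}

largest_component <- function(mask, d) {
  labels <- cpp_label_components(as.logical(mask), d, 26L)
  nlab <- attr(labels, "n_components")
  if (nlab == 0L) stop("volume has no foreground")
  sizes <- tabulate(labels, nbins = nlab)
  array(labels == which.max(sizes), dim = d)
}

#' Extract the shaft centerline of the dominant component
#'
#' Computes the anisotropic Euclidean distance transform of the largest
#' 26-connected component and traces the longest medial path through it: a
#' double Dijkstra sweep (geodesic-diameter heuristic) with step costs
#' penalised away from the distance-transform ridge, so the path follows the
#' centre of the shaft even around bends. Per-point radius comes from the
#' distance transform (half-voxel surface correction applied downstream).
#'
#' @param volume a [binary_volume()] with one dominant elongated component.
#' @param medialness_gamma strength of the ridge-following penalty.
#' @param smooth_window running-mean window (points) applied to the path.
#' @return A `shaft_axis`: tibble with `x`, `y`, `z`, `radius`, `arclen` (um)
#'   and the component mask in the `"component"` attribute.
#' @export
extract_shaft_axis <- function(volume, medialness_gamma = 8, smooth_window = 7) {
  stopifnot(inherits(volume, "binary_volume"))
  d <- dim(volume$mask)
  sp <- volume$spacing
  if (!any(volume$mask)) stop("volume has no foreground")
  comp <- largest_component(volume$mask, d)
  edt <- cpp_distance_to_set(!comp, d, sp[["dy"]], sp[["dx"]], sp[["dz"]])
  edt[!comp] <- 0
  rmax <- max(edt)
  cost <- 1 + medialness_gamma * (1 - edt / rmax)^2
  # run the diameter sweeps on the thick core of the component (largest
  # connected region of high distance transform), so a long thin spine can
  # never become an axis endpoint; spine necks fall below the core threshold
  # and disconnect their heads from the core
  core <- array(edt >= 0.5 * rmax, dim = d)
  core_cc <- cpp_label_components(as.logical(core), d, 26L)
  ncc <- attr(core_cc, "n_components")
  if (ncc >= 1L && sum(core) >= 30) {
    sizes <- tabulate(core_cc, nbins = ncc)
    core <- array(core_cc == which.max(sizes), dim = d)
  } else {
    core <- comp
  }
  cv <- as.logical(core)
  seed0 <- which.max(ifelse(cv, edt, -1)) - 1L
  g1 <- cpp_geodesic(cv, d, sp[["dy"]], sp[["dx"]], sp[["dz"]], seed0, cost)
  e1 <- which.max(ifelse(is.finite(g1$dist), g1$dist, -1)) - 1L
  g2 <- cpp_geodesic(cv, d, sp[["dy"]], sp[["dx"]], sp[["dz"]], e1, cost)
  e2 <- which.max(ifelse(is.finite(g2$dist), g2$dist, -1)) - 1L
  # walk parents from e2 back to e1
  path <- integer(0)
  v <- e2
  while (v >= 0) {
    path <- c(path, v)
    v <- g2$parent[v + 1L]
  }
  path <- rev(path) + 1L
  coords <- index_to_coord(d, path, sp)
  radius <- edt[path]
  # smooth the voxel-quantised path; the radius profile gets a wide running
  # median first, so spine attachments do not inflate the local shaft radius
  xs <- running_mean(coords[, "x"], smooth_window)
  ys <- running_mean(coords[, "y"], smooth_window)
  zs <- running_mean(coords[, "z"], smooth_window)
  if (length(radius) >= 5) {
    k <- min(31L, length(radius) - (1 - length(radius) %% 2))
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) radius <- stats::runmed(radius, k)
  }
  radius <- running_mean(radius, smooth_window)
  arclen <- cumsum(c(0, sqrt(diff(xs)^2 + diff(ys)^2 + diff(zs)^2)))
  if (max(arclen) < 2 * 2 * rmax) {
    stop("largest component is not elongated (length < 2 x diameter)")
  }
  axis <- tibble(x = xs, y = ys, z = zs, radius = radius, arclen = arclen)
  class(axis) <- c("shaft_axis", class(axis))
  attr(axis, "component") <- comp
  attr(axis, "spacing") <- sp
  axis
}

# squared distances from points (n x 3) to each axis point; returns nearest
# axis index and distance, chunked to bound memory
nearest_axis_point <- function(pts, axis_xyz, chunk = 4000L) {
  n <- nrow(pts)
  idx <- integer(n)
  dist <- numeric(n)
  a2 <- rowSums(axis_xyz^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), a2, `+`) - 2 * block %*% t(axis_xyz)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
  }
  list(index = idx, dist = dist)
}

#' Segment spine candidates off the shaft envelope
#'
#' Foreground voxels of the shaft component farther from the centerline than
#' the local shaft radius plus a margin form protrusion candidates;
#' 26-connected candidates touching the shaft envelope become spine
#' subvolumes, anchored at their closest-to-axis voxel. Candidates whose
#' radial extent is below `noise_floor` um are discarded. Two spines that
#' merge into one candidate are flagged `contact_ambiguous` rather than
#' silently split.
#'
#' @param volume a [binary_volume()].
#' @param axis a `shaft_axis` from [extract_shaft_axis()] (computed if NULL).
#' @param margin envelope margin beyond the local radius, um (default: one
#'   voxel diagonal in-plane).
#' @param noise_floor minimal radial extent of a real protrusion, um.
#' @param ambiguous_span arclength span of the contact patch above which a
#'   candidate is flagged contact-ambiguous, um.
#' @return A list of spine candidates: each has `voxels` (linear indices),
#'   `attachment_index`, `attachment` (um coords), `branch_arclen`,
#'   `radial_extent`, `contact_ambiguous`.
#' @export
segment_spines <- function(volume, axis = NULL, margin = NULL, noise_floor = 0.2,
                           ambiguous_span = 1.5) {
  stopifnot(inherits(volume, "binary_volume"))
  if (is.null(axis)) axis <- extract_shaft_axis(volume)
  sp <- volume$spacing
  d <- dim(volume$mask)
  margin <- margin %||% (1.2 * max(sp[["dx"]], sp[["dy"]]))
  comp <- attr(axis, "component")
  fg <- which(comp)
  if (!length(fg)) return(list())
  pts <- index_to_coord(d, fg, sp)
  axis_xyz <- cbind(axis$x, axis$y, axis$z)
  near <- nearest_axis_point(pts, axis_xyz)
  r_local <- axis$radius[near$index]

  # anisotropic envelope: brightfield axial elongation (and axial PSF blur)
  # dilates the shaft along z, so the local shaft surface is modelled as an
  # ellipse with axial semi-axis kappa * r. kappa is estimated from the
  # component's own surface voxels that lie along z from the axis; it is ~1
  # for unblurred masks.
  dz_frac2 <- ((pts[, "z"] - axis_xyz[near$index, 3]) / pmax(near$dist, 1e-9))^2
  on_surface <- fg %in% surface_voxels(comp, d)
  axial_surf <- on_surface & dz_frac2 > 0.7 & near$dist > 0
  kappa <- if (sum(axial_surf) >= 20) {
    clamp(median(near$dist[axial_surf] / r_local[axial_surf]), 1, 3)
  } else 1
  r_eff <- r_local * sqrt(1 + (kappa^2 - 1) * dz_frac2)
  radial <- near$dist - r_eff
  cand <- radial > margin
  if (!any(cand)) return(list())
  cand_mask <- array(FALSE, dim = d)
  cand_mask[fg[cand]] <- TRUE
  labels <- cpp_label_components(as.logical(cand_mask), d, 26L)
  nlab <- attr(labels, "n_components")
  radial_fg <- numeric(length(comp))
  radial_fg[fg] <- radial
  arclen_fg <- numeric(length(comp))
  arclen_fg[fg] <- axis$arclen[near$index]
  # split candidates whose arclength footprint carries several distinct
  # radial peaks (spines fused through blur halo); candidates with a wide
  # footprint but no clear valley stay merged and are flagged ambiguous
  split_candidate <- function(vox) {
    al <- arclen_fg[vox]
    span <- diff(range(al))
    if (span <= 1.2) return(list(vox))
    bw <- 0.25
    bins <- floor((al - min(al)) / bw)
    prof <- tapply(radial_fg[vox], bins, max)
    full <- rep(0, max(bins) + 1)
    full[as.integer(names(prof)) + 1] <- prof
    sm <- running_mean(full, 3)
    nb <- length(sm)
    peaks <- which(sm >= c(sm[-1], -Inf) & sm >= c(-Inf, sm[-nb]) &
                     sm > noise_floor + margin)
    if (length(peaks) < 2) return(list(vox))
    cuts <- integer(0)
    for (i in seq_len(length(peaks) - 1)) {
      seg <- peaks[i]:peaks[i + 1]
      valley <- seg[which.min(sm[seg])]
      if (sm[valley] < 0.55 * min(sm[peaks[i]], sm[peaks[i + 1]])) {
        cuts <- c(cuts, valley)
      }
    }
    if (!length(cuts)) return(list(vox))
    grp <- findInterval(bins + 1, cuts, rightmost.closed = FALSE) + 1L
    unname(split(vox, grp))
  }

  out <- list()
  for (lab in seq_len(nlab)) {
    vox0 <- which(labels == lab)
    if (length(vox0) < 4L) next
    if (max(radial_fg[vox0]) < noise_floor) next
    for (vox in split_candidate(vox0)) {
    if (length(vox) < 4L) next
    ext <- max(radial_fg[vox])
    if (ext < noise_floor) next
    # anchor the attachment beneath the radial apex, not at the global
    # closest-to-shaft voxel (which can sit far along a low roughness ridge)
    apex0 <- vox[which.max(radial_fg[vox])]
    apex0_xyz <- index_to_coord(d, apex0, sp)
    vox_xyz <- index_to_coord(d, vox, sp)
    near_apex <- sqrt(rowSums(sweep(vox_xyz, 2, drop(apex0_xyz))^2)) <= ext + 0.3
    att <- vox[near_apex][which.min(radial_fg[vox[near_apex]])]
    # must touch the envelope: closest voxel within ~1 voxel of the margin shell
    if (radial_fg[att] > margin + 1.8 * max(sp)) next
    contact <- vox[radial_fg[vox] <= margin + 1.8 * max(sp)]
    span <- diff(range(arclen_fg[contact]))
    att_axis_i <- near$index[match(att, fg)]
    att_axis_pt <- axis_xyz[att_axis_i, ]
    att_coord <- drop(index_to_coord(d, att, sp))
    # outward direction: height-weighted centroid of the protrusion relative
    # to its axis anchor (robust against flat or tilted tips)
    vc <- index_to_coord(d, vox, sp)
    wts <- pmax(radial_fg[vox], 0)^2
    ctr_dir <- colSums(sweep(vc, 2, att_axis_pt) * wts) / sum(wts)
    # end-cap suppression: the centerline stops about one radius inside the
    # rounded shaft ends, so the caps register as protrusions pointing along
    # the axis; a genuine spine near an end still points radially
    att_arclen <- arclen_fg[att]
    end_zone <- axis$radius[c(1, nrow(axis))] + 2 * margin + 0.3
    near_start <- att_arclen < end_zone[1]
    near_end <- att_arclen > max(axis$arclen) - end_zone[2]
    if (near_start || near_end) {
      k <- min(5L, nrow(axis))
      tang <- if (near_start) {
        unit(c(axis$x[k] - axis$x[1], axis$y[k] - axis$y[1], axis$z[k] - axis$z[1]))
      } else {
        n_ax <- nrow(axis)
        unit(c(axis$x[n_ax] - axis$x[n_ax - k + 1], axis$y[n_ax] - axis$y[n_ax - k + 1],
               axis$z[n_ax] - axis$z[n_ax - k + 1]))
      }
      if (abs(sum(unit(ctr_dir) * tang)) > 0.6) next
    }
    # the attachment point lies on the shaft surface by definition: project
    # the anchor onto the local envelope along the outward direction
    att_surface <- att_axis_pt + unit(ctr_dir) * r_local[match(att, fg)]
    names(att_surface) <- c("x", "y", "z")
    out[[length(out) + 1L]] <- list(
      voxels = vox,
      heights = radial_fg[vox],          # radial height of each voxel above the shaft surface
      attachment_index = att,
      attachment = att_surface,
      outward = unit(ctr_dir),
      axis_point = att_axis_pt,
      branch_arclen = arclen_fg[att],
      radial_extent = ext,
      shaft_radius = r_local[match(att, fg)],
      contact_ambiguous = span > ambiguous_span
    )
    }
  }
  attr(out, "margin") <- margin
  out
}

#' Measure one spine
#'
#' Works on the spine's voxel subvolume: geodesic distances from the
#' attachment give the protrusion length and the attachment-to-tip path; a
#' slab-based cross-section profile along that path locates the neck (width
#' minimum in the proximal portion) and the head compartment (distal of the
#' neck). Diameters use volume-equivalent estimators (cylinder for the neck,
#' sphere for the head), which are far more robust at 0.1 um voxels than
#' inradius estimates. A neck is present when the head/neck ratio reaches the
#' neck detection ratio (1.2) and the profile genuinely dips. Protrusions are
#' counted as distinct distal compartments under a sweep of geodesic-distance
#' cuts; head sphericity compares the head's equivalent-sphere surface to its
#' (corrected) voxel surface; spinules are small clusters protruding beyond
#' the head sphere.
#'
#' @param subvolume logical 3D array containing one spine (TRUE voxels), or a
#'   [binary_volume()].
#' @param attachment voxel index triplet `c(y, x, z)` (1-based) of the
#'   attachment voxel, or its linear index.
#' @param spacing a [voxel_spacing()].
#' @param rules a [spine_rules()] list (measurement knobs live there too).
#' @param base_offset distance (um) between the true shaft surface and the
#'   proximal face of the subvolume (the envelope margin removed by
#'   [segment_spines()]); added back to length measurements. Ignored when
#'   `heights` is given.
#' @param heights optional per-voxel radial heights above the shaft surface
#'   (um), aligned with `which(subvolume)`, as produced by
#'   [segment_spines()]. When given, the width profile is taken over radial
#'   shells (the faithful cross-sections for protrusions off a shaft);
#'   otherwise geodesic distance from the attachment is used.
#' @return A one-row tibble of spine features.
#' @export
measure_spine <- function(subvolume, attachment, spacing, rules = spine_rules(),
                          base_offset = 0, heights = NULL, outward = NULL,
                          axis_point = NULL) {
  if (inherits(subvolume, "binary_volume")) {
    spacing <- subvolume$spacing
    subvolume <- subvolume$mask
  }
  d <- dim(subvolume)
  if (sum(subvolume) < 2) stop("spine subvolume smaller than 2 voxels")
  if (length(attachment) == 3L) {
    attachment <- linear_index(d, attachment[1], attachment[2], attachment[3])
  }
  if (!subvolume[attachment]) stop("attachment voxel is not foreground")
  sp <- spacing
  hbar <- mean(c(sp[["dx"]], sp[["dy"]], sp[["dz"]]))
  voxvol <- sp[["dx"]] * sp[["dy"]] * sp[["dz"]]

  geo <- cpp_geodesic(as.logical(subvolume), d, sp[["dy"]], sp[["dx"]], sp[["dz"]],
                      attachment - 1L, numeric(0))
  reach <- is.finite(geo$dist) & as.logical(subvolume)
  gd <- geo$dist
  tip <- which.max(ifelse(reach, gd, -1))

  vox_all <- which(subvolume)
  if (is.null(heights)) {
    pos_all <- gd[vox_all]
    pos_all[!is.finite(pos_all)] <- 0
    pos_all <- pos_all + base_offset
  } else {
    stopifnot(length(heights) == length(vox_all))
    pos_all <- heights
  }
  keep <- reach[vox_all]
  vox <- vox_all[keep]
  pos <- pos_all[keep]
  vcoord <- index_to_coord(d, vox, sp)
  vgeo <- gd[vox]

  # cross-section profile over position shells of one voxel thickness
  H <- max(pos)
  centers <- seq(min(pos), H, by = hbar)
  if (length(centers) < 2) centers <- c(min(pos), H)
  width_at <- function(cc) {
    count <- sum(abs(pos - cc) <= 0.5 * hbar)
    2 * sqrt(count * voxvol / hbar / pi)
  }
  wprof <- running_mean(vapply(centers, width_at, 0), 3)
  n_p <- length(centers)

  # robust tip: when the profile carries a distal bulb (a head that may bear
  # spinules), the tip anchor is the farthest shell still carrying a
  # substantial cross-section, so a spinule cannot drag the head anchor (or
  # the length) past the head. Monotone profiles (stubby/wide bumps) have no
  # spinules and keep their true apex.
  dist_idx <- which(centers >= 0.55 * H)
  if (!length(dist_idx)) dist_idx <- n_p
  w_dist_max <- max(wprof[dist_idx])
  mid_idx <- which(centers <= 0.5 * H)
  if (!length(mid_idx)) mid_idx <- 1L
  bulb <- w_dist_max > 1.25 * min(wprof[mid_idx])
  H_star <- if (bulb) {
    solid <- centers[wprof >= 0.45 * w_dist_max]
    if (length(solid)) max(solid) + 0.5 * hbar else H
  } else {
    H + 0.5 * hbar
  }
  total_len <- H_star

  # head: the distal compartment anchored at the (robust) tip, by fixed-point
  # iteration — take all voxels within one head diameter of the tip,
  # re-estimate the diameter from the compartment volume (equivalent
  # sphere), repeat
  d_head <- w_dist_max
  for (it in 1:4) {
    in_head <- pos >= H_star - d_head & pos <= H_star
    head_vol <- max(sum(in_head), 1) * voxvol
    d_new <- (6 * head_vol / pi)^(1 / 3)
    if (abs(d_new - d_head) < 0.01) { d_head <- d_new; break }
    d_head <- d_new
  }
  head_diameter <- d_head
  b_head <- H_star - d_head            # proximal boundary of the head
  in_head <- pos >= b_head
  head_vox <- vox[in_head]
  head_xyz <- vcoord[in_head, , drop = FALSE]
  head_centroid <- if (length(head_vox) > 1) colMeans(head_xyz) else drop(head_xyz)
  head_vol <- length(head_vox) * voxvol
  i_headc <- which.min(abs(centers - (H - d_head / 2)))
  w_head0 <- wprof[i_headc]

  # neck: narrowest shell proximal of the head compartment
  prox <- which(centers < b_head)
  if (!length(prox)) prox <- seq_len(max(1L, floor(n_p / 2)))
  i_neck <- prox[which.min(wprof[prox])]
  g_neck <- centers[i_neck]

  # lateral (base) extent for the neckless stubby/wide rules: widest extent
  # perpendicular to the outward direction when known, else widest shell
  base_diameter <- if (!is.null(outward) && !is.null(axis_point)) {
    rel <- sweep(vcoord, 2, as.numeric(axis_point)[1:3])
    along <- as.vector(rel %*% unit(outward))
    perp <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
    2 * max(perp) + 0.25 * hbar
  } else {
    max(wprof[prox])
  }

  # neck diameter: volume-equivalent cylinder over a window around the neck
  neck_lo <- max(min(pos), g_neck - 0.15)
  neck_hi <- min(g_neck + 0.15, b_head)
  in_neck <- pos >= neck_lo & pos <= neck_hi
  if (sum(in_neck) >= 2 && neck_hi > neck_lo) {
    neck_area <- sum(in_neck) * voxvol / max(neck_hi - neck_lo, hbar)
    neck_diameter <- 2 * sqrt(neck_area / pi)
  } else {
    neck_diameter <- wprof[i_neck]
  }
  neck_diameter <- max(neck_diameter, 0.5 * hbar)

  # distinct minimum: the neck must genuinely be narrower than the head's
  # own profile width
  distinct_min <- wprof[i_neck] < 0.9 * w_head0
  neck_present <- (head_diameter / neck_diameter >= rules$neck_ratio) && distinct_min
  neck_length <- if (neck_present) max(0, b_head) else 0

  # protrusion count: sweep geodesic cuts through the distal half and count
  # substantial compartments
  n_prot <- 1L
  min_prot_vox <- rules$min_protrusion_voxels
  for (f in seq(0.5, 0.9, by = 0.08)) {
    cut <- f * gd[tip]
    sel <- vgeo > cut
    if (sum(sel) < 2 * min_prot_vox) next
    cm <- array(FALSE, dim = d)
    cm[vox[sel]] <- TRUE
    lab <- cpp_label_components(as.logical(cm), d, 26L)
    sizes <- tabulate(lab, nbins = attr(lab, "n_components"))
    k <- sum(sizes >= min_prot_vox)
    if (k > n_prot) n_prot <- k
  }

  # head sphericity: equivalent-sphere surface / corrected voxel surface
  head_mask <- array(FALSE, dim = d)
  head_mask[head_vox] <- TRUE
  surf <- voxel_surface_area(head_mask, sp)
  sphere_surf <- pi^(1 / 3) * (6 * head_vol)^(2 / 3)
  head_shape <- clamp(sphere_surf / (surf * 2 / 3), 0, 1)

  # spinules: small clusters protruding beyond the head sphere
  spinule_count <- 0L
  if (length(head_vox) > 8) {
    rad <- sqrt(rowSums(sweep(head_xyz, 2, head_centroid)^2))
    outer_vox <- head_vox[rad > head_diameter / 2 + 0.5 * hbar]
    if (length(outer_vox) >= 2) {
      om <- array(FALSE, dim = d)
      om[outer_vox] <- TRUE
      lab <- cpp_label_components(as.logical(om), d, 26L)
      sizes <- tabulate(lab, nbins = attr(lab, "n_components"))
      max_vox <- (rules$spinule_max_length + 0.15) * (rules$spinule_max_diameter + 0.1)^2 *
        pi / 4 / voxvol
      spinule_count <- sum(sizes >= 2 & sizes <= max_vox)
    }
  }

  tibble(
    neck_present = neck_present,
    neck_length = neck_length,
    neck_diameter = neck_diameter,
    head_diameter = head_diameter,
    base_diameter = base_diameter,
    n_protrusions = as.integer(n_prot),
    head_shape = head_shape,
    protrusion_length = total_len,
    spinule_count = as.integer(spinule_count)
  )
}

# total face area of the boundary between mask and non-mask (6-connectivity)
voxel_surface_area <- function(mask, sp) {
  d <- dim(mask)
  area <- 0
  faces <- list(
    list(ax = 1, a = sp[["dx"]] * sp[["dz"]]),
    list(ax = 2, a = sp[["dy"]] * sp[["dz"]]),
    list(ax = 3, a = sp[["dx"]] * sp[["dy"]])
  )
  for (f in faces) {
    n <- d[f$ax]
    shift_lo <- switch(f$ax,
      mask[c(1, seq_len(n - 1)), , , drop = FALSE],
      mask[, c(1, seq_len(n - 1)), , drop = FALSE],
      mask[, , c(1, seq_len(n - 1)), drop = FALSE]
    )
    # interior transitions + both outer faces
    trans <- sum(mask != shift_lo)
    edge_faces <- switch(f$ax,
      sum(mask[1, , ]) + sum(mask[n, , ]),
      sum(mask[, 1, ]) + sum(mask[, n, ]),
      sum(mask[, , 1]) + sum(mask[, , n])
    )
    area <- area + f$a * (trans + edge_faces)
  }
  area
}
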