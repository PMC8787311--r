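# The 3D spine-reconstruction pipeline: outlier removal, unsharp + edge-aware
# enhancement, per-slice adaptive binarisation, false-positive pruning,
# per-slice flood fill and cubic z interpolation, orchestrated by
# reconstruct_spines(). Stages are pure: each takes and returns a container
# and appends to its provenance.

#' Binary volume
#'
#' A 3D boolean mask aligned to an [image_stack()] grid, with spacing and an
#' ordered provenance of applied stages.
#'
#' @param mask logical `[y, x, z]` array.
#' @param spacing a [voxel_spacing()].
#' @param provenance list of `list(stage = , params = )` entries.
#' @return A `binary_volume` object.
#' @export
binary_volume <- function(mask, spacing, provenance = list()) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  structure(list(mask = mask, spacing = spacing, provenance = provenance),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_volume: %d x %d px, %d slice(s); %d fg voxels (%.2f%%)\n",
              d[2], d[1], d[3], sum(x$mask), 100 * mean(x$mask)))
  if (length(x$provenance)) {
    cat("stages:", paste(vapply(x$provenance, `[[`, "", "stage"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.binary_volume <- function(x) dim(x$mask)

add_provenance <- function(vol, stage, params) {
  vol$provenance <- c(vol$provenance, list(list(stage = stage, params = params)))
  vol
}

#' Reconstruction pipeline configuration
#'
#' Central home for every numeric parameter of the pipeline stages. Defaults
#' are scaled to spine-stack geometry (0.1 um z-steps, sub-micron necks).
#' Intensity-valued parameters (`outlier_k` is a robust-z multiple;
#' `adaptive_offset` and `edge_aware_sigma_r` are on the normalized 0..1
#' scale).
#'
#' @param outlier_window odd window (voxels) for the outlier detector.
#' @param outlier_k robust-z threshold (multiples of the MAD-scaled spread).
#' @param median_prefilter apply a 3D median prefilter in small subvolumes
#'   before outlier removal (aggressive: erodes sub-voxel necks; off by
#'   default).
#' @param median_subvolume odd window (voxels) of the median prefilter.
#' @param unsharp_amount unsharp-mask strength (0 disables).
#' @param unsharp_sigma unsharp Gaussian sigma, um (lateral).
#' @param unsharp_sigma_z axial unsharp sigma, um; larger than lateral by
#'   default to counteract brightfield axial elongation.
#' @param edge_aware_sigma_s spatial sigma of the domain-transform filter, um.
#' @param edge_aware_sigma_r range sigma (normalized intensity); `Inf`
#'   disables the smoothing pass.
#' @param edge_aware_iters recursive-filter iterations.
#' @param unsharp_first unsharp masking before (TRUE) or after the edge-aware
#'   pass.
#' @param adaptive_block odd 2D block (pixels) of the per-slice local mean.
#' @param adaptive_offset threshold offset below/above the local mean
#'   (normalized intensity).
#' @param polarity `"dark_foreground"` (brightfield) or `"bright_foreground"`.
#' @param min_object_voxels components smaller than this are dropped unless
#'   attached.
#' @param attach_radius maximal distance (um) from the largest component at
#'   which a small component still counts as attached.
#' @param zfactor integer z-upsampling factor of the cubic interpolation
#'   stage (1 = keep sampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outlier_window = 3, outlier_k = 4,
                            median_prefilter = FALSE, median_subvolume = 3,
                            unsharp_amount = 1.0, unsharp_sigma = 0.2,
                            unsharp_sigma_z = 0.4,
                            edge_aware_sigma_s = 1.0, edge_aware_sigma_r = 0.35,
                            edge_aware_iters = 3, unsharp_first = TRUE,
                            adaptive_block = 31, adaptive_offset = 5 / 255,
                            polarity = c("dark_foreground", "bright_foreground"),
                            min_object_voxels = 30, attach_radius = 0.5,
                            zfactor = 3) {
  polarity <- match.arg(polarity)
  cfg <- list(outlier_window = as.integer(outlier_window), outlier_k = outlier_k,
              median_prefilter = isTRUE(median_prefilter),
              median_subvolume = as.integer(median_subvolume),
              unsharp_amount = unsharp_amount, unsharp_sigma = unsharp_sigma,
              unsharp_sigma_z = unsharp_sigma_z,
              edge_aware_sigma_s = edge_aware_sigma_s,
              edge_aware_sigma_r = edge_aware_sigma_r,
              edge_aware_iters = as.integer(edge_aware_iters),
              unsharp_first = isTRUE(unsharp_first),
              adaptive_block = as.integer(adaptive_block),
              adaptive_offset = adaptive_offset, polarity = polarity,
              min_object_voxels = as.integer(min_object_voxels),
              attach_radius = attach_radius, zfactor = as.integer(zfactor))
  if (cfg$outlier_window %% 2L == 0L || cfg$adaptive_block %% 2L == 0L ||
      cfg$median_subvolume %% 2L == 0L || cfg$outlier_window < 3L ||
      cfg$adaptive_block < 3L) {
    stop("window/block sizes must be odd and >= 3")
  }
  if (cfg$zfactor < 1L) stop("zfactor must be >= 1")
  structure(cfg, class = "pipeline_config")
}

# normalize a stack to float 0..1
as_float <- function(stack) {
  if (stack$depth == "float") return(stack)
  div <- switch(stack$depth, uint8 = 255, uint16 = 65535)
  image_stack(stack$voxels / div, stack$spacing, depth = "float", meta = stack$meta)
}

#' Outlier removal (impulse detection)
#'
#' Replaces a voxel with its local median when it deviates from that median
#' by more than `k` times the MAD-scaled local spread AND has at most
#' `isolation_max` similar neighbours in the window (an isolated impulse).
#' The isolation guard is what distinguishes silver-precipitate dots and hot
#' pixels from genuine thin structure such as spine necks, which always carry
#' several similar neighbours. Optionally preceded by a 3D median prefilter
#' in small subvolumes.
#'
#' @param stack an [image_stack()] (8-bit or normalized).
#' @param window odd window size in voxels.
#' @param k robust-z threshold; `Inf` disables replacement.
#' @param isolation_max maximal number of similar window voxels for a voxel
#'   to count as an impulse.
#' @param median_prefilter apply the median prefilter first.
#' @return The filtered [image_stack()].
#' @export
remove_outliers <- function(stack, window = 3, k = 4, isolation_max = 2,
                            median_prefilter = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (window >= min(d[1:2]) && window >= d[3]) stop("window larger than stack extent")
  v <- stack$voxels
  if (median_prefilter) {
    mm <- cpp_local_median_mad(as.numeric(v), dim(v), as.integer(window))
    v <- array(mm$median, dim = d)
  }
  if (is.infinite(k)) {
    out <- stack
    out$voxels <- v
    return(out)
  }
  mm <- cpp_local_median_mad(as.numeric(v), dim(v), as.integer(window))
  med <- array(mm$median, dim = d)
  spread <- 1.4826 * array(mm$mad, dim = d)
  dev <- abs(v - med)
  outlier <- dev > k * spread & dev > 0
  if (any(outlier)) {
    # isolation guard: count similar neighbours (within half the deviation)
    idx <- which(outlier)
    nbr_similar <- count_similar_neighbours(v, idx, dev[idx])
    keep_structure <- nbr_similar > isolation_max
    idx <- idx[!keep_structure]
    v[idx] <- med[idx]
  }
  out <- stack
  out$voxels <- v
  out
}

# number of 26-neighbours of each voxel in idx whose intensity is within half
# the voxel's own deviation from it
count_similar_neighbours <- function(v, idx, dev) {
  d <- dim(v)
  z <- (idx - 1) %/% (d[1] * d[2])
  rem <- (idx - 1) %% (d[1] * d[2])
  x <- rem %/% d[1]
  y <- rem %% d[1]
  counts <- integer(length(idx))
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dz == 0 && dx == 0 && dy == 0) next
    yy <- clamp(y + dy, 0, d[1] - 1)
    xx <- clamp(x + dx, 0, d[2] - 1)
    zz <- clamp(z + dz, 0, d[3] - 1)
    nid <- yy + d[1] * (xx + d[2] * zz) + 1
    counts <- counts + as.integer(abs(v[nid] - v[idx]) < 0.5 * dev)
  }
  counts
}

#' Edge enhancement: unsharp masking plus edge-aware smoothing
#'
#' `clip(x + amount * (x - G_sigma(x)))` followed by a recursive
#' domain-transform filter (normalized-convolution style recursive filtering)
#' that smooths within near-constant regions while preserving intensity
#' discontinuities. `sigma_r = Inf` makes the smoothing a passthrough. The
#' two passes can be swapped with `unsharp_first`.
#'
#' @param stack a normalized (float) or 8-bit [image_stack()].
#' @param unsharp_amount,unsharp_sigma unsharp parameters (sigma in um).
#' @param edge_aware_sigma_s,edge_aware_sigma_r,edge_aware_iters
#'   domain-transform parameters (spatial sigma um, range sigma normalized).
#' @param unsharp_first order of the two passes.
#' @return A float [image_stack()] in 0..1.
#' @export
enhance_edges <- function(stack, unsharp_amount = 1.0, unsharp_sigma = 0.2,
                          unsharp_sigma_z = NULL,
                          edge_aware_sigma_s = 1.0, edge_aware_sigma_r = 0.35,
                          edge_aware_iters = 3, unsharp_first = TRUE) {
  stack <- as_float(stack)
  sp <- stack$spacing
  v <- stack$voxels
  unsharp_sigma_z <- unsharp_sigma_z %||% unsharp_sigma
  unsharp <- function(v) {
    if (unsharp_amount <= 0) return(v)
    sig <- c(unsharp_sigma / sp[["dy"]], unsharp_sigma / sp[["dx"]],
             unsharp_sigma_z / sp[["dz"]])
    g <- blur_gaussian(v, sig)
    clamp(v + unsharp_amount * (v - g), 0, 1)
  }
  smooth <- function(v) {
    if (is.infinite(edge_aware_sigma_r)) return(v)
    domain_transform_filter(v, sp, edge_aware_sigma_s, edge_aware_sigma_r,
                            edge_aware_iters)
  }
  v <- if (unsharp_first) smooth(unsharp(v)) else unsharp(smooth(v))
  out <- stack
  out$voxels <- clamp(v, 0, 1)
  out
}

# Recursive domain-transform filter (Gastal & Oliveira style RF), applied
# along each axis per iteration. The domain-transform increments are computed
# once from the input (the guide), so edges found in the raw data gate the
# smoothing at every iteration. sigma_s in um, sigma_r in normalized
# intensity.
domain_transform_filter <- function(v, spacing, sigma_s, sigma_r, iters = 3) {
  d <- dim(v)
  steps <- c(spacing[["dy"]], spacing[["dx"]], spacing[["dz"]])
  ratio <- sigma_s / sigma_r
  perms <- list(c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))   # move axis to last dim
  invs  <- list(c(3, 1, 2), c(1, 3, 2), c(1, 2, 3))
  # per-axis domain-transform increments from the guide (input) image
  guide_inc <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    w <- aperm(v, perms[[ax]])
    mw <- matrix(w, ncol = n)
    guide_inc[[ax]] <- steps[ax] + ratio * abs(mw[, -1, drop = FALSE] -
                                                 mw[, -n, drop = FALSE])
  }
  for (it in seq_len(iters)) {
    sigma_h <- sigma_s * sqrt(3) * 2^(iters - it) / sqrt(4^iters - 1)
    a <- exp(-sqrt(2) / sigma_h)
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 2) next
      w <- aperm(v, perms[[ax]])
      dp <- dim(w)
      mw <- matrix(w, ncol = n)
      wgt <- a^guide_inc[[ax]]
      for (i in 2:n) {
        mw[, i] <- mw[, i] + wgt[, i - 1] * (mw[, i - 1] - mw[, i])
      }
      for (i in (n - 1):1) {
        mw[, i] <- mw[, i] + wgt[, i] * (mw[, i + 1] - mw[, i])
      }
      v <- aperm(array(mw, dim = dp), invs[[ax]])
    }
  }
  v
}

#' Adaptive (local-mean) binarisation
#'
#' Per-slice 2D thresholding: each pixel's threshold is the mean over an odd
#' `block`-sized neighbourhood (edge-replicated) minus `offset` for
#' dark-foreground polarity (strictly below threshold is foreground), or plus
#' `offset` for bright foreground. Constant regions yield background.
#'
#' @param stack an [image_stack()] (normalized internally).
#' @param block odd block size (pixels).
#' @param offset threshold offset, normalized intensity.
#' @param polarity `"dark_foreground"` or `"bright_foreground"`.
#' @return A [binary_volume()].
#' @export
binarize_adaptive <- function(stack, block = 31, offset = 5 / 255,
                              polarity = c("dark_foreground", "bright_foreground")) {
  polarity <- match.arg(polarity)
  if (block %% 2L == 0L || block < 3L) stop("block must be odd and >= 3")
  stack <- as_float(stack)
  v <- stack$voxels
  d <- dim(v)
  mask <- array(FALSE, dim = d)
  for (i in seq_len(d[3])) {
    mu <- local_mean_2d(v[, , i], block)
    # strict inequality with a numerical guard so exact ties resolve to
    # background regardless of summation order
    mask[, , i] <- if (polarity == "dark_foreground") {
      v[, , i] < mu - offset - 1e-9
    } else {
      v[, , i] > mu + offset + 1e-9
    }
  }
  binary_volume(mask, stack$spacing,
                provenance = list(list(stage = "binarize_adaptive",
                                       params = list(block = block, offset = offset,
                                                     polarity = polarity))))
}

# 2D local mean over an odd block with edge replication, via integral image
local_mean_2d <- function(img, block) {
  r <- block %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[clamp(seq_len(ny + 2 * r) - r, 1L, ny),
             clamp(seq_len(nx + 2 * r) - r, 1L, nx), drop = FALSE]
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  y1 <- seq_len(ny); y2 <- y1 + 2 * r
  x1 <- seq_len(nx); x2 <- x1 + 2 * r
  s <- ii[y2 + 1, x2 + 1] - ii[y1, x2 + 1] - ii[y2 + 1, x1] + ii[y1, x1]
  s / (block * block)
}

#' Prune false positives
#'
#' Keeps a 26-connected component iff it has at least `min_object_voxels`
#' voxels OR lies within `attach_radius` um of the largest component (a
#' small object attached to the dendrite is a spine candidate, a distant one
#' is an artifact). Output is a subset of the input.
#'
#' @param volume a [binary_volume()].
#' @param min_object_voxels size threshold (voxels).
#' @param attach_radius attachment distance, um.
#' @return The pruned [binary_volume()].
#' @export
prune_false_positives <- function(volume, min_object_voxels = 30, attach_radius = 0.5) {
  stopifnot(inherits(volume, "binary_volume"))
  d <- dim(volume$mask)
  if (!any(volume$mask)) {
    warning("prune_false_positives: empty input volume")
    return(add_provenance(volume, "prune_false_positives",
                          list(min_object_voxels = min_object_voxels,
                               attach_radius = attach_radius)))
  }
  labels <- cpp_label_components(as.logical(volume$mask), d, 26L)
  nlab <- attr(labels, "n_components")
  sizes <- tabulate(labels, nbins = nlab)
  largest <- which.max(sizes)
  sp <- volume$spacing
  keep <- sizes >= min_object_voxels
  keep[largest] <- TRUE
  if (!all(keep)) {
    dist_to_largest <- cpp_distance_to_set(labels == largest, d,
                                           sp[["dy"]], sp[["dx"]], sp[["dz"]])
    fg <- which(labels > 0)
    min_dist <- tapply(dist_to_largest[fg], labels[fg], min)
    keep <- keep | (min_dist <= attach_radius)
  }
  newmask <- array(labels > 0 & keep[pmax(labels, 1)], dim = d)
  out <- volume
  out$mask <- newmask
  add_provenance(out, "prune_false_positives",
                 list(min_object_voxels = min_object_voxels,
                      attach_radius = attach_radius))
}

#' Per-slice 2D flood fill
#'
#' In every slice, background regions not 4-connected to the slice border are
#' filled as foreground (closing hollow cross-sections left by adaptive
#' thresholding of wide shafts). Output is a superset of the input.
#'
#' @param volume a [binary_volume()].
#' @return The filled [binary_volume()].
#' @export
flood_fill_slices <- function(volume) {
  stopifnot(inherits(volume, "binary_volume"))
  d <- dim(volume$mask)
  filled <- cpp_fill_slices(as.logical(volume$mask), d)
  out <- volume
  out$mask <- array(filled, dim = d)
  add_provenance(out, "flood_fill_slices", list())
}

#' Cubic z interpolation of a binary volume
#'
#' Lifts the mask to a 0/1 field, interpolates along z with a Catmull-Rom
#' cubic (per-voxel-column), re-thresholds at 0.5 and divides `dz` by
#' `zfactor`. Output has `(n - 1) * zfactor + 1` slices and reproduces the
#' original masks at the original slice positions. With fewer than 4 slices
#' the interpolation falls back to linear with a warning.
#'
#' @param volume a [binary_volume()].
#' @param zfactor integer upsampling factor (>= 1).
#' @return The interpolated [binary_volume()].
#' @export
interpolate_z <- function(volume, zfactor = 3) {
  stopifnot(inherits(volume, "binary_volume"))
  zfactor <- as.integer(zfactor)
  if (zfactor < 1L) stop("zfactor must be >= 1")
  if (zfactor == 1L) {
    return(add_provenance(volume, "interpolate_z", list(zfactor = 1L)))
  }
  d <- dim(volume$mask)
  n <- d[3]
  linear <- n < 4L
  if (linear) warning("fewer than 4 slices: falling back to linear z interpolation")
  m <- (n - 1L) * zfactor + 1L
  field <- array(as.numeric(volume$mask), dim = d)
  out <- array(FALSE, dim = c(d[1], d[2], m))
  slice <- function(i) field[, , clamp(i, 1L, n)]
  for (j in seq_len(m)) {
    tglob <- (j - 1) / zfactor          # position in input-slice units
    i <- floor(tglob)
    u <- tglob - i
    i <- as.integer(i) + 1L             # 1-based left slice
    if (u == 0) {
      out[, , j] <- field[, , i] > 0.5
    } else if (linear) {
      val <- (1 - u) * slice(i) + u * slice(i + 1L)
      out[, , j] <- val > 0.5
    } else {
      # Catmull-Rom weights
      w0 <- -0.5 * u^3 + u^2 - 0.5 * u
      w1 <- 1.5 * u^3 - 2.5 * u^2 + 1
      w2 <- -1.5 * u^3 + 2 * u^2 + 0.5 * u
      w3 <- 0.5 * u^3 - 0.5 * u^2
      val <- w0 * slice(i - 1L) + w1 * slice(i) + w2 * slice(i + 1L) + w3 * slice(i + 2L)
      out[, , j] <- val > 0.5
    }
  }
  sp <- volume$spacing
  res <- binary_volume(out, voxel_spacing(sp[["dx"]], sp[["dy"]], sp[["dz"]] / zfactor),
                       provenance = volume$provenance)
  add_provenance(res, "interpolate_z", list(zfactor = zfactor))
}

#' Run the full spine-reconstruction pipeline
#'
#' Applies, in order: (a) outlier removal, (b) unsharp + edge-aware
#' enhancement, (c) per-slice adaptive binarisation, (d) false-positive
#' pruning, (e) per-slice flood fill, (f) cubic z interpolation. The final
#' stage (g) of the original workflow — visualization — is realised as export
#' ([write_mask()]), not an interactive viewer. Provenance records every
#' stage with its parameters; a summary (component count, foreground
#' fraction) is attached as the `"summary"` attribute.
#'
#' @param stack an [image_stack()] (8-bit or normalized grayscale).
#' @param config a [pipeline_config()].
#' @return A [binary_volume()] of dendritic shafts and spines.
#' @export
reconstruct_spines <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "pipeline_config"))
  x <- as_float(stack)
  x <- remove_outliers(x, window = config$outlier_window, k = config$outlier_k,
                       median_prefilter = config$median_prefilter)
  prov <- list(list(stage = "remove_outliers",
                    params = config[c("outlier_window", "outlier_k", "median_prefilter")]))
  x <- enhance_edges(x, unsharp_amount = config$unsharp_amount,
                     unsharp_sigma = config$unsharp_sigma,
                     unsharp_sigma_z = config$unsharp_sigma_z,
                     edge_aware_sigma_s = config$edge_aware_sigma_s,
                     edge_aware_sigma_r = config$edge_aware_sigma_r,
                     edge_aware_iters = config$edge_aware_iters,
                     unsharp_first = config$unsharp_first)
  prov <- c(prov, list(list(stage = "enhance_edges",
                            params = config[c("unsharp_amount", "unsharp_sigma",
                                              "edge_aware_sigma_s", "edge_aware_sigma_r")])))
  vol <- binarize_adaptive(x, block = config$adaptive_block,
                           offset = config$adaptive_offset,
                           polarity = config$polarity)
  vol$provenance <- c(prov, vol$provenance)
  vol <- prune_false_positives(vol, config$min_object_voxels, config$attach_radius)
  vol <- flood_fill_slices(vol)
  vol <- interpolate_z(vol, config$zfactor)
  labels <- cpp_label_components(as.logical(vol$mask), dim(vol$mask), 26L)
  attr(vol, "summary") <- list(
    n_components = attr(labels, "n_components"),
    foreground_fraction = mean(vol$mask)
  )
  vol
}

#' Write a binary volume as an 8-bit mask TIFF
#'
#' @param volume a [binary_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(volume, path) {
  stopifnot(inherits(volume, "binary_volume"))
  stack <- image_stack(array(255 * as.numeric(volume$mask), dim = dim(volume$mask)),
                       volume$spacing, depth = "uint8")
  write_stack(stack, path)
}

#' Read an 8-bit mask TIFF back as a binary volume
#'
#' @param path TIFF path (with spacing sidecar).
#' @param spacing optional [voxel_spacing()] override.
#' @return A [binary_volume()].
#' @export
read_mask <- function(path, spacing = NULL) {
  stack <- read_stack(path, spacing)
  binary_volume(stack$voxels > 127, stack$spacing,
                provenance = list(list(stage = "read_mask", params = list(path = path))))
}
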