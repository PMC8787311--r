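#' Voxel spacing in micrometres
#'
#' Physical size of one voxel along each axis. `dz` is the focal step of the
#' z-stack and may differ from the in-plane pixel size (anisotropic stacks:
#' whole neurons are typically imaged at 0.5 um z-steps, spine segments at
#' 0.1 um).
#'
#' @param dx,dy,dz um per voxel along x, y and z. `dy` and `dz` default to
#'   `dx` (isotropic).
#' @return A `voxel_spacing` object (named numeric vector).
#' @examples
#' voxel_spacing(0.1, 0.1, 0.1)
#' voxel_spacing(0.2, dz = 0.5)
#' @export
voxel_spacing <- function(dx, dy = dx, dz = dx) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("voxel spacing must be strictly positive and finite")
  }
  structure(s, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx=%g dy=%g dz=%g um\n", x["dx"], x["dy"], x["dz"]))
  invisible(x)
}

#' 3D image stack
#'
#' The unit of image I/O and processing: a grid of intensities with physical
#' voxel spacing. Grayscale stacks are stored as `[y, x, z]` arrays (slice
#' order = z order, top-left origin, voxel-centre convention: voxel
#' `(j, k, i)` sits at physical `(k*dx, j*dy, i*dz)` with 0-based offsets).
#' RGB stacks carry a 4th channel dimension (`[y, x, z, 3]`) and must be
#' collapsed with [to_monochrome8()] before quantitative processing.
#'
#' @param voxels numeric array: `[y, x, z]` (grayscale, a matrix is promoted
#'   to one slice) or `[y, x, z, 3]` (RGB).
#' @param spacing a [voxel_spacing()].
#' @param depth declared intensity range: `"uint8"` (0..255), `"uint16"`
#'   (0..65535) or `"float"` (0..1).
#' @param meta free-form acquisition metadata (list).
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing, depth = c("uint8", "uint16", "float"),
                        meta = list()) {
  depth <- match.arg(depth)
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || !(length(dim(voxels)) %in% c(3L, 4L))) {
    stop("voxels must be a [y, x, z] or [y, x, z, 3] array")
  }
  if (length(dim(voxels)) == 4L && dim(voxels)[4] != 3L) {
    stop("channel dimension must have length 3 (RGB)")
  }
  if (any(dim(voxels)[1:3] < 1L)) stop("stack must have at least one slice and nonzero extent")
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  rng <- switch(depth, uint8 = c(0, 255), uint16 = c(0, 65535), float = c(0, 1))
  v <- range(voxels)
  if (v[1] < rng[1] - 1e-9 || v[2] > rng[2] + 1e-9) {
    stop(sprintf("intensities outside declared %s range [%g, %g]", depth, rng[1], rng[2]))
  }
  structure(list(voxels = voxels, spacing = spacing, depth = depth, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d px, %d slice(s)%s, %s\n", d[2], d[1], d[3],
              if (length(d) == 4L) ", RGB" else "", x$depth))
  print(x$spacing)
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

is_rgb <- function(stack) length(dim(stack$voxels)) == 4L

#' Convert a stack to 8-bit monochrome
#'
#' RGB input is collapsed with ITU-R 601 luminance weights
#' (0.299, 0.587, 0.114); 16-bit input is rescaled by a full-range linear
#' map (65535 -> 255); float input in 0..1 is scaled by 255. Already-8-bit
#' grayscale input is returned unchanged.
#'
#' @param stack an [image_stack()].
#' @return An 8-bit grayscale `image_stack`.
#' @export
to_monochrome8 <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (is_rgb(stack)) {
    w <- c(0.299, 0.587, 0.114)
    v <- v[, , , 1, drop = FALSE] * w[1] + v[, , , 2, drop = FALSE] * w[2] +
      v[, , , 3, drop = FALSE] * w[3]
    dim(v) <- dim(v)[1:3]
  }
  v <- switch(stack$depth,
    uint8  = v,
    uint16 = v * (255 / 65535),
    float  = v * 255
  )
  if (stack$depth == "uint8" && !is_rgb(stack)) return(stack)
  image_stack(round(v), stack$spacing, depth = "uint8",
              meta = c(stack$meta, list(converted_from = stack$depth)))
}

#' Invert luminosity of an 8-bit stack
#'
#' Maps every voxel v to 255 - v, turning dark Golgi-impregnated structure on
#' a bright ground into bright structure on dark ground. An involution.
#'
#' @param stack an 8-bit grayscale [image_stack()].
#' @return The inverted `image_stack`; spacing and shape are preserved.
#' @export
invert_luminosity <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$depth != "uint8" || is_rgb(stack)) {
    stop("invert_luminosity requires an 8-bit grayscale stack")
  }
  out <- stack
  out$voxels <- 255 - stack$voxels
  out
}

#' 2D composite of a z-stack across focal planes
#'
#' Combines all focal planes into one 2D reconstruction. For brightfield
#' stacks (dark structure on bright ground) the default is the per-pixel
#' minimum across z, so in-focus dark structure from any plane survives;
#' `"mean"` and `"sum_clipped"` (sum clipped to the intensity ceiling) are
#' available as alternatives.
#'
#' @param stack a grayscale [image_stack()] with at least one slice.
#' @param method `"min"` (default), `"mean"` or `"sum_clipped"`.
#' @return A 2D matrix `[y, x]` with the stack's spacing attached as the
#'   `"spacing"` attribute.
#' @export
composite_projection <- function(stack, method = c("min", "mean", "sum_clipped")) {
  stopifnot(inherits(stack, "image_stack"))
  if (is_rgb(stack)) stop("project after to_monochrome8()")
  method <- match.arg(method)
  v <- stack$voxels
  nz <- dim(v)[3]
  slices <- lapply(seq_len(nz), function(i) v[, , i])
  ceiling_ <- switch(stack$depth, uint8 = 255, uint16 = 65535, float = 1)
  proj <- switch(method,
    min = Reduce(pmin, slices),
    mean = Reduce(`+`, slices) / nz,
    sum_clipped = clamp(Reduce(`+`, slices), 0, ceiling_)
  )
  attr(proj, "spacing") <- stack$spacing
  proj
}
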