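# TIFF stack I/O. One page per z slice; spacing is echoed into a JSON
# sidecar ({dx, dy, dz, bit_depth}) next to the TIFF because plain TIFF
# carries no reliable physical-unit tags.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")

#' Read a TIFF z-stack
#'
#' Reads a single- or multi-page grayscale or RGB TIFF into an
#' [image_stack()], pages in z order. RGB input is kept as RGB — it is not
#' silently converted (use [to_monochrome8()]). Voxel spacing comes from the
#' `spacing` argument or, if that is `NULL`, from the JSON sidecar written by
#' [write_stack()].
#'
#' @param path path to a TIFF file.
#' @param spacing a [voxel_spacing()], or `NULL` to read the sidecar.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  dims <- lapply(pages, function(p) dim(p)[1:2])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("TIFF pages have inconsistent dimensions")
  }
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  integerish <- is.numeric(pages[[1]]) && max(vapply(pages, max, 0)) > 1 + 1e-9
  depth <- if (!integerish && bits > 8) "float" else if (bits > 8) "uint16" else "uint8"
  rgb <- length(dim(pages[[1]])) == 3L
  if (rgb && dim(pages[[1]])[3] == 4L) pages <- lapply(pages, function(p) p[, , 1:3])
  if (rgb && !(dim(pages[[1]])[3] %in% c(3L, 4L))) stop("unsupported sample format")
  ny <- dims[[1]][1]; nx <- dims[[1]][2]; nz <- length(pages)
  if (rgb) {
    v <- array(0, dim = c(ny, nx, nz, 3L))
    for (i in seq_len(nz)) v[, , i, ] <- pages[[i]][, , 1:3]
  } else {
    v <- array(unlist(pages, use.names = FALSE), dim = c(ny, nx, nz))
  }
  if (is.null(spacing)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop("no spacing given and no sidecar found at ", sc)
    }
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    spacing <- voxel_spacing(meta$dx, meta$dy, meta$dz)
  }
  image_stack(v, spacing, depth = depth, meta = list(source = path, bits_per_sample = bits))
}

#' Write a stack as a multi-page TIFF
#'
#' Writes one lossless 8-bit page per slice plus a JSON spacing sidecar.
#' Float stacks (0..1) are only written when `quantize = TRUE`, which maps
#' them to 8-bit by `round(v * 255)`; without the flag this is an error so
#' no precision is dropped silently.
#'
#' @param stack an [image_stack()].
#' @param path output path (`.tif`).
#' @param quantize allow quantizing a float stack to 8-bit.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, quantize = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (stack$depth == "float") {
    if (!quantize) stop("float stack: pass quantize = TRUE to write as 8-bit")
    v <- round(v * 255)
  } else if (stack$depth == "uint16") {
    stop("write 16-bit stacks after to_monochrome8()")
  }
  nz <- dim(v)[3]
  pages <- lapply(seq_len(nz), function(i) {
    if (is_rgb(stack)) v[, , i, ] / 255 else v[, , i] / 255
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW"),
                 error = function(e) stop("cannot write TIFF at ", path, ": ", conditionMessage(e)))
  sp <- stack$spacing
  jsonlite::write_json(
    list(dx = sp[["dx"]], dy = sp[["dy"]], dz = sp[["dz"]], bit_depth = 8L),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
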