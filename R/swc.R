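#' Neuron morphology (SWC semantics)
#'
#' A rooted tree of 3D points with radii: each node is
#' `(id, type, x, y, z, radius, parent)` in micrometres, `parent = -1` marks
#' the root, and connected nodes define tapering cylinder (frustum)
#' compartments. Structure codes follow the SWC convention (1 = soma,
#' 2 = axon, 3 = dendrite, 4 = apical dendrite).
#'
#' @param nodes a data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return A `neuron_morphology` (a tibble subclass).
#' @export
neuron_morphology <- function(nodes) {
  nodes <- as_tibble(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("nodes must have columns: ", paste(need, collapse = ", "))
  }
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  validate_morphology(nodes)
  class(nodes) <- c("neuron_morphology", class(nodes))
  nodes
}

validate_morphology <- function(nodes) {
  if (nrow(nodes) == 0L) stop("morphology has no nodes")
  if (anyDuplicated(nodes$id)) stop("duplicate node id: ",
                                    nodes$id[duplicated(nodes$id)][1])
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) stop("morphology must have exactly one root (parent -1), found ",
                                length(roots))
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0)) {
    stop("all radii must be strictly positive")
  }
  idx <- match(nodes$parent, nodes$id)
  dangling <- nodes$parent != -1L & is.na(idx)
  if (any(dangling)) {
    stop("dangling parent reference: node ", nodes$id[which(dangling)[1]],
         " points to missing id ", nodes$parent[which(dangling)[1]])
  }
  # cycle / connectivity check: every node must reach the root
  n <- nrow(nodes)
  reached <- logical(n)
  for (i in seq_len(n)) {
    j <- i
    hop <- 0L
    while (!is.na(j) && !reached[j]) {
      hop <- hop + 1L
      if (hop > n) stop("cycle detected in morphology")
      if (nodes$parent[j] == -1L) { reached[j] <- TRUE; break }
      j <- idx[j]
    }
    # mark path as reached
    j <- i
    while (!is.na(j) && !reached[j]) { reached[j] <- TRUE; j <- idx[j] }
  }
  invisible(nodes)
}

#' Read an SWC morphology file
#'
#' Standard whitespace-delimited 7-column SWC with `#` comments. The tree is
#' validated: duplicate ids, dangling parents, cycles and nonpositive radii
#' are distinct errors.
#'
#' @param path path to an `.swc` file.
#' @return A [neuron_morphology()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("cannot read SWC: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("SWC file has no data rows: ", path)
  tab <- read.table(text = lines, col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  neuron_morphology(tab)
}

#' Write an SWC morphology file
#'
#' @param m a [neuron_morphology()].
#' @param path output path.
#' @param comment optional header comment line(s).
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path, comment = NULL) {
  stopifnot(inherits(m, "neuron_morphology"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     m$id, m$type, m$x, m$y, m$z, m$radius, m$parent), con)
  invisible(path)
}

# children ids indexed by node position
child_index <- function(m) {
  idx <- match(m$parent, m$id)
  split(seq_len(nrow(m)), factor(idx, levels = seq_len(nrow(m))))
}

soma_rows <- function(m) which(m$type == 1L)
dendrite_rows <- function(m) which(m$type %in% c(3L, 4L))

#' Apply a rigid motion and/or uniform scaling to a morphology
#'
#' Coordinates become `scale * (R %*% x) + translate`; radii are multiplied
#' by `scale`. Useful for invariance checks and for re-framing a
#' reconstruction in anatomical coordinates.
#'
#' @param m a [neuron_morphology()].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translate length-3 offset in um.
#' @param scale positive scalar.
#' @return The transformed [neuron_morphology()].
#' @export
transform_morphology <- function(m, rotation = diag(3), translate = c(0, 0, 0),
                                 scale = 1) {
  stopifnot(inherits(m, "neuron_morphology"), scale > 0)
  xyz <- t(rotation %*% t(as.matrix(m[, c("x", "y", "z")]))) * scale
  m$x <- xyz[, 1] + translate[1]
  m$y <- xyz[, 2] + translate[2]
  m$z <- xyz[, 3] + translate[3]
  m$radius <- m$radius * scale
  m
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param deg angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), deg) {
  axis <- match.arg(axis)
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}
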