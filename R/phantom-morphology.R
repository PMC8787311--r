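# Synthetic spindle-neuron morphologies. The generator's defaults encode the
# study conditions: an elongated fusiform soma (37 x 19 um by default), two
# thick primary dendrites leaving opposite somatic poles close to the
# vertical axis, and a branching continuum from straight (rare branches) to
# profuse radial ramification.

#' Parameters of the spindle-neuron generator
#'
#' @param soma_length soma major axis, um.
#' @param soma_diameter soma maximal minor axis, um (must be < `soma_length`
#'   for the spindle phenotype).
#' @param n_primary number of primary dendrites; 2 for the spindle phenotype.
#'   Values > 2 produce additional oblique primaries (a pyramidal-like
#'   control).
#' @param primary_angle_spread maximal deviation of a primary departure from
#'   the vertical axis, degrees.
#' @param branch_profile `"straight"` (no collaterals), `"sparse"` or
#'   `"profuse"`.
#' @param collateral_angle_range degrees (min, max) between a collateral and
#'   its parent shaft.
#' @param primary_diameter basal diameter of the primary shafts, um.
#' @param total_extent tip-to-tip vertical extent of the cell, um.
#' @param seed RNG seed; the same params + seed give a byte-identical SWC.
#' @return A `spindle_params` list.
#' @export
spindle_params <- function(soma_length = 37, soma_diameter = 19, n_primary = 2,
                           primary_angle_spread = 10,
                           branch_profile = c("sparse", "straight", "profuse"),
                           collateral_angle_range = c(40, 80),
                           primary_diameter = 2.6,
                           total_extent = 260, seed = 1L) {
  branch_profile <- match.arg(branch_profile)
  p <- list(soma_length = soma_length, soma_diameter = soma_diameter,
            n_primary = as.integer(n_primary),
            primary_angle_spread = primary_angle_spread,
            branch_profile = branch_profile,
            collateral_angle_range = collateral_angle_range,
            primary_diameter = primary_diameter,
            total_extent = total_extent, seed = as.integer(seed))
  if (p$soma_length <= p$soma_diameter) {
    stop("spindle phenotype requires soma_length > soma_diameter")
  }
  if (p$n_primary < 1L) stop("n_primary must be >= 1")
  if (p$total_extent <= p$soma_length) {
    stop("total_extent must exceed soma_length")
  }
  structure(p, class = "spindle_params")
}

new_node_buffer <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$next_id <- 1L
  env
}

add_node <- function(buf, type, x, y, z, radius, parent) {
  id <- buf$next_id
  buf$rows[[id]] <- list(id = id, type = type, x = x, y = y, z = z,
                         radius = radius, parent = parent)
  buf$next_id <- id + 1L
  id
}

# grow a wiggly shaft from `origin` along `dir`; returns id of last node
grow_shaft <- function(buf, origin, dir, length_um, r0, r1, parent_id,
                       step = 4, wiggle_deg = 4, type = 3L) {
  n_step <- max(2L, ceiling(length_um / step))
  pos <- origin
  d <- unit(dir)
  parent <- parent_id
  radii <- seq(r0, r1, length.out = n_step)
  for (i in seq_len(n_step)) {
    jitter_axis <- orthogonal_unit(d + runif(3, -0.1, 0.1))
    d <- unit(rotate_about(d, jitter_axis, runif(1, -wiggle_deg, wiggle_deg)))
    # pull back toward the nominal direction so the shaft stays straight
    d <- unit(0.75 * d + 0.25 * unit(dir))
    pos <- pos + d * (length_um / n_step)
    parent <- add_node(buf, type, pos[1], pos[2], pos[3], radii[i], parent)
  }
  parent
}

#' Generate a spindle-neuron SWC morphology
#'
#' Builds a rooted SWC tree: a prolate soma in the 3-point convention
#' (centre node plus two pole nodes on the major axis), one ascending and one
#' descending primary shaft leaving the opposite poles within
#' `primary_angle_spread` of the vertical (+y) axis, linearly tapering radii,
#' and collateral branches according to `branch_profile`. Deterministic for a
#' fixed seed.
#'
#' @param params a [spindle_params()].
#' @return A [neuron_morphology()].
#' @export
generate_spindle_swc <- function(params = spindle_params()) {
  stopifnot(inherits(params, "spindle_params"))
  with_seed(params$seed, {
    L <- params$soma_length
    D <- params$soma_diameter
    buf <- new_node_buffer()
    # 3-point soma along +y
    root <- add_node(buf, 1L, 0, 0, 0, D / 2, -1L)
    add_node(buf, 1L, 0, -L / 2, 0, D / 2, root)
    add_node(buf, 1L, 0, L / 2, 0, D / 2, root)

    shaft_len <- (params$total_extent - L) / 2
    r0 <- params$primary_diameter / 2
    rate <- switch(params$branch_profile, straight = 0, sparse = 1 / 40,
                   profuse = 1 / 12)

    grow_primary <- function(sign_y) {
      theta <- runif(1, 0, params$primary_angle_spread)
      phi <- runif(1, 0, 360)
      d0 <- c(0, sign_y, 0)
      d <- rotate_about(d0, orthogonal_unit(d0), theta)
      d <- rotate_about(d, d0, phi)
      origin <- c(0, sign_y * L / 2, 0)
      first <- add_node(buf, 3L, origin[1], origin[2], origin[3], r0, root)
      # grow in branching-aware chunks
      grow_rec <- function(start_id, start_pos, dir, len, r_start, depth) {
        n_col <- if (rate > 0) rpois(1, rate * len) else 0L
        bp <- sort(runif(n_col, 0.15, 0.9)) * len
        segs <- diff(c(0, bp, len))
        pos <- start_pos
        parent <- start_id
        r_here <- r_start
        travelled <- 0
        for (k in seq_along(segs)) {
          r_next <- r_start * (1 - 0.7 * (travelled + segs[k]) / len)
          parent <- grow_shaft(buf, pos, dir, segs[k], r_here, r_next, parent)
          pos <- unlist(buf$rows[[parent]][c("x", "y", "z")])
          travelled <- travelled + segs[k]
          r_here <- r_next
          if (k <= length(bp) && depth < 2) {
            ang <- runif(1, params$collateral_angle_range[1],
                         params$collateral_angle_range[2])
            cd <- rotate_about(dir, orthogonal_unit(dir), ang)
            cd <- rotate_about(cd, dir, runif(1, 0, 360))
            clen <- runif(1, 0.2, 0.5) * (len - travelled) + 8
            grow_rec(parent, pos, unit(cd), clen, r_here * 0.55, depth + 1)
          }
        }
        parent
      }
      grow_rec(first, origin, unit(d), shaft_len, r0, 0L)
    }

    grow_primary(1)
    grow_primary(-1)
    if (params$n_primary > 2L) {
      for (i in seq_len(params$n_primary - 2L)) {
        phi <- 360 * i / (params$n_primary - 2L) + runif(1, -10, 10)
        d <- rotate_about(c(0, 1, 0), c(0, 0, 1), 90 + runif(1, -25, 25))
        d <- rotate_about(d, c(0, 1, 0), phi)
        origin <- unit(d) * c(D / 2, L / 2, D / 2) * 0.9
        first <- add_node(buf, 3L, origin[1], origin[2], origin[3],
                          r0 * runif(1, 0.8, 1.0), 1L)
        grow_shaft(buf, origin, d, shaft_len * runif(1, 0.4, 0.7),
                   r0 * 0.9, r0 * 0.25, first)
      }
    }
    neuron_morphology(bind_rows(lapply(buf$rows, as_tibble)))
  })
}

# Serpentine dendritic segment: a single spiny dendrite folded through a
# small imaging volume, used as the carrier for spine-scale phantoms. The
# path is built from straight runs along x joined by right-angle connectors,
# scaled so the total arclength is `target_length`.
segment_phantom <- function(target_length = 75, field = c(12.7, 12.7, 15.0),
                            radius = 0.35, node_step = 0.45) {
  rows_y <- c(2.8, 6.35, 9.9)
  layers_z <- c(4.5, 10.5)
  x_lo <- 1.75
  conn <- 4 * diff(rows_y)[1] + diff(layers_z)[1]
  run_len <- (target_length - conn) / 6
  x_hi <- x_lo + run_len
  stopifnot(x_hi < field[1] - 1.6)
  pts <- list()
  push_seg <- function(from, to) {
    len <- vec_norm(to - from)
    n <- max(1L, ceiling(len / node_step))
    for (i in seq_len(n)) pts[[length(pts) + 1L]] <<- from + (to - from) * i / n
  }
  waypoints <- list(
    c(x_lo, rows_y[1], layers_z[1]), c(x_hi, rows_y[1], layers_z[1]),
    c(x_hi, rows_y[2], layers_z[1]), c(x_lo, rows_y[2], layers_z[1]),
    c(x_lo, rows_y[3], layers_z[1]), c(x_hi, rows_y[3], layers_z[1]),
    c(x_hi, rows_y[3], layers_z[2]), c(x_lo, rows_y[3], layers_z[2]),
    c(x_lo, rows_y[2], layers_z[2]), c(x_hi, rows_y[2], layers_z[2]),
    c(x_hi, rows_y[1], layers_z[2]), c(x_lo, rows_y[1], layers_z[2])
  )
  pts[[1]] <- waypoints[[1]]
  for (i in seq_len(length(waypoints) - 1)) push_seg(waypoints[[i]], waypoints[[i + 1]])
  nodes <- tibble(
    id = seq_along(pts),
    type = 3L,
    x = vapply(pts, `[`, 0, 1),
    y = vapply(pts, `[`, 0, 2),
    z = vapply(pts, `[`, 0, 3),
    radius = radius,
    parent = c(-1L, seq_len(length(pts) - 1L))
  )
  neuron_morphology(nodes)
}
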