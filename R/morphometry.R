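# Cylinder-model morphometry of SWC reconstructions: soma metrics, branch
# counting by topological decomposition, total dendritic length and frustum
# volume, and the geometric spindle-phenotype qualifier.

#' Soma metrics
#'
#' Length is the extent of soma node centres along the first principal axis,
#' the main diameter is twice the largest soma radius (orthogonal extent for
#' multi-node somata if larger), and the volume uses a prolate-ellipsoid
#' model `(4/3) * pi * (L/2) * (D/2)^2` — consistent with a spindle/rod cell
#' body. For a single-node (spherical) soma this reduces to `(4/3) * pi * r^3`.
#'
#' @param m a [neuron_morphology()] with soma nodes (type 1).
#' @return A one-row tibble: `soma_length`, `soma_max_diameter`,
#'   `soma_volume` (um, um, um^3).
#' @export
soma_metrics <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  rows <- soma_rows(m)
  if (length(rows) == 0L) stop("morphology has no soma nodes (type 1)")
  xyz <- as.matrix(m[rows, c("x", "y", "z")])
  rad <- m$radius[rows]
  if (length(rows) == 1L) {
    L <- 2 * rad
    D <- 2 * rad
  } else {
    pc <- prcomp(xyz, center = TRUE)
    proj <- xyz %*% pc$rotation
    L <- diff(range(proj[, 1]))
    ortho <- if (ncol(proj) >= 2) diff(range(proj[, 2])) else 0
    D <- max(2 * max(rad), ortho)
    if (L < D) { tmp <- L; L <- D; D <- tmp }
  }
  tibble(soma_length = L, soma_max_diameter = D,
         soma_volume = (4 / 3) * pi * (L / 2) * (D / 2)^2)
}

frustum_volume <- function(h, r1, r2) pi * h * (r1^2 + r1 * r2 + r2^2) / 3

# rows (positions) of primary dendrites: dendritic children of soma nodes
primary_rows <- function(m) {
  pidx <- match(m$parent, m$id)
  which(m$type %in% c(3L, 4L) & !is.na(pidx) & m$type[pidx] == 1L)
}

# descendant rows of a dendritic node (within dendritic types), inclusive
dendritic_subtree_rows <- function(m, start_row) {
  pidx <- match(m$parent, m$id)
  kids <- split(seq_len(nrow(m)), pidx[seq_len(nrow(m))])
  out <- integer(0)
  stack <- start_row
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    ch <- ch[m$type[ch] %in% c(3L, 4L)]
    stack <- c(stack, ch)
  }
  out
}

#' Dendritic tree metrics
#'
#' Implements the cylinder-model quantities: the total number of branches is
#' the count of unbranched segments delimited by primary origins, branching
#' points and terminal tips (so a primary that splits once contributes 3);
#' total length is the sum of Euclidean inter-node distances over dendritic
#' edges; total volume is the sum of per-edge frustum volumes
#' `pi * h * (r1^2 + r1*r2 + r2^2) / 3`. Edges from a soma node to the first
#' dendritic node lie inside the soma and are excluded from length/volume;
#' the primary shaft diameter is twice the radius of that first node.
#'
#' @param m a [neuron_morphology()] with at least one dendritic node.
#' @return A list: `n_branches`, `total_length`, `total_volume`,
#'   `primary_shaft_diameters` (named by primary node id), and `per_primary`,
#'   a tibble with one row per primary dendrite (id, n_branches, length,
#'   volume).
#' @export
dendrite_metrics <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  dend <- dendrite_rows(m)
  if (length(dend) == 0L) stop("morphology has no dendritic nodes")
  pidx <- match(m$parent, m$id)
  prim <- primary_rows(m)
  if (length(prim) == 0L) {
    # dendritic root without soma (e.g. an isolated segment): treat the root
    # of each dendritic component as its primary origin
    prim <- which(m$type %in% c(3L, 4L) &
                    (m$parent == -1L | !(m$type[pidx] %in% c(3L, 4L))))
  }
  kids <- split(seq_len(nrow(m)), pidx[seq_len(nrow(m))])
  dend_children <- function(v) {
    ch <- kids[[as.character(v)]]
    ch[m$type[ch] %in% c(3L, 4L)]
  }
  per <- purrr::map(prim, function(p) {
    n_seg <- 0L
    len <- 0
    vol <- 0
    # walk segments from the primary origin
    starts <- list(p)
    while (length(starts)) {
      v <- starts[[1]]
      starts <- starts[-1]
      repeat {
        ch <- dend_children(v)
        if (length(ch) == 1L) {
          len <- len + sqrt(sum((unlist(m[ch, c("x", "y", "z")]) -
                                   unlist(m[v, c("x", "y", "z")]))^2))
          vol <- vol + frustum_volume(
            sqrt(sum((unlist(m[ch, c("x", "y", "z")]) -
                        unlist(m[v, c("x", "y", "z")]))^2)),
            m$radius[v], m$radius[ch])
          v <- ch
        } else {
          n_seg <- n_seg + 1L
          if (length(ch) > 1L) {
            for (c2 in ch) {
              len <- len + sqrt(sum((unlist(m[c2, c("x", "y", "z")]) -
                                       unlist(m[v, c("x", "y", "z")]))^2))
              vol <- vol + frustum_volume(
                sqrt(sum((unlist(m[c2, c("x", "y", "z")]) -
                            unlist(m[v, c("x", "y", "z")]))^2)),
                m$radius[v], m$radius[c2])
            }
            starts <- c(starts, as.list(ch))
          }
          break
        }
      }
    }
    tibble(primary_id = m$id[p], n_branches = n_seg, length = len, volume = vol)
  }) %>% bind_rows()
  list(
    n_branches = sum(per$n_branches),
    total_length = sum(per$length),
    total_volume = sum(per$volume),
    primary_shaft_diameters = setNames(2 * m$radius[prim], m$id[prim]),
    per_primary = per
  )
}

#' One-row morphometry report
#'
#' Combines [soma_metrics()] and [dendrite_metrics()] into a single flat row
#' suitable for cohort tables. Soma volume is reported separately and is not
#' included in the dendritic volume.
#'
#' @param m a [neuron_morphology()].
#' @return A one-row tibble of class `morphometry_report`.
#' @export
morphometry_report <- function(m) {
  sm <- tryCatch(soma_metrics(m), error = function(e) {
    tibble(soma_length = NA_real_, soma_max_diameter = NA_real_, soma_volume = NA_real_)
  })
  dm <- dendrite_metrics(m)
  out <- tibble(
    soma_length = sm$soma_length,
    soma_max_diameter = sm$soma_max_diameter,
    soma_volume = sm$soma_volume,
    n_primary = nrow(dm$per_primary),
    primary_shaft_diameter_mean = mean(dm$primary_shaft_diameters),
    n_branches = dm$n_branches,
    total_dendritic_length = dm$total_length,
    total_dendritic_volume = dm$total_volume
  )
  attr(out, "per_primary") <- dm$per_primary
  class(out) <- c("morphometry_report", class(out))
  out
}

#' @export
glance.neuron_morphology <- function(x, ...) {
  r <- morphometry_report(x)
  class(r) <- setdiff(class(r), "morphometry_report")
  attr(r, "per_primary") <- NULL
  r
}

#' @export
tidy.morphometry_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Spindle-neuron qualifier
#'
#' Evaluates the geometric inclusion criteria for the spindle phenotype:
#' exactly two substantial primary dendrites (basal diameter at least
#' `min_rel_diameter` of the thickest), emerging from opposite somatic poles
#' (angle between departure directions >= `min_pole_angle` degrees), each
#' within `max_vertical_angle` degrees of the declared vertical (pial) axis,
#' and an elongated soma (`L/D >= min_elongation`). SWC carries no anatomical
#' frame, so the vertical axis is supplied by the caller.
#'
#' @param m a [neuron_morphology()].
#' @param vertical_axis length-3 vector pointing from white matter to pia.
#' @param min_rel_diameter,min_pole_angle,max_vertical_angle,min_elongation
#'   criterion thresholds (see above).
#' @return An object of class `spindle_qualifier`: list with `is_spindle`
#'   and a per-criterion tibble (use [tidy()] to extract it).
#' @export
classify_spindle <- function(m, vertical_axis = c(0, 1, 0),
                             min_rel_diameter = 0.6, min_pole_angle = 150,
                             max_vertical_angle = 30, min_elongation = 1.6) {
  stopifnot(inherits(m, "neuron_morphology"))
  prim <- primary_rows(m)
  if (length(prim) == 0L) stop("morphology has no primary dendrites")
  axis <- unit(vertical_axis)
  soma <- soma_rows(m)
  centroid <- colMeans(as.matrix(m[soma, c("x", "y", "z")]))

  # departure direction: soma centroid -> 5th node along the primary (or tip)
  departure <- function(p) {
    path <- p
    pidx <- match(m$parent, m$id)
    kids <- split(seq_len(nrow(m)), pidx[seq_len(nrow(m))])
    v <- p
    while (length(path) < 5L) {
      ch <- kids[[as.character(v)]]
      ch <- ch[m$type[ch] %in% c(3L, 4L)]
      if (length(ch) != 1L) break
      v <- ch
      path <- c(path, v)
    }
    tip <- path[length(path)]
    unit(unlist(m[tip, c("x", "y", "z")]) - centroid)
  }

  diams <- 2 * m$radius[prim]
  substantial <- diams >= min_rel_diameter * max(diams)
  prim_sub <- prim[substantial]
  crit1 <- sum(substantial) == 2L

  if (sum(substantial) >= 2L) {
    dirs <- lapply(prim_sub[order(-diams[substantial])][1:2], departure)
    pole_angle <- angle_deg(dirs[[1]], dirs[[2]])
    vert <- vapply(dirs, function(d) min(angle_deg(d, axis), angle_deg(d, -axis)), 0)
    crit2 <- pole_angle >= min_pole_angle
    crit3 <- all(vert <= max_vertical_angle)
  } else {
    pole_angle <- NA_real_
    vert <- NA_real_
    crit2 <- FALSE
    crit3 <- FALSE
  }

  sm <- soma_metrics(m)
  elong <- sm$soma_length / sm$soma_max_diameter
  crit4 <- elong >= min_elongation

  report <- tibble(
    criterion = c("two_primary_dendrites", "opposite_poles",
                  "vertical_orientation", "soma_elongation"),
    value = c(sum(substantial), pole_angle, max(vert), elong),
    threshold = c(2, min_pole_angle, max_vertical_angle, min_elongation),
    pass = c(crit1, crit2, crit3, crit4)
  )
  structure(list(is_spindle = all(report$pass), criteria = report),
            class = "spindle_qualifier")
}

#' @export
print.spindle_qualifier <- function(x, ...) {
  cat("spindle qualifier:", if (x$is_spindle) "ACCEPTED" else "REJECTED", "\n")
  print(x$criteria)
  invisible(x)
}

#' @export
tidy.spindle_qualifier <- function(x, ...) x$criteria

#' @export
glance.spindle_qualifier <- function(x, ...) {
  tibble(is_spindle = x$is_spindle, n_criteria = nrow(x$criteria),
         n_pass = sum(x$criteria$pass))
}
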