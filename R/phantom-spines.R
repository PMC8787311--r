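# Ground-truth spine decoration. Spine classes follow the qualitative
# taxonomy (thin, stubby, wide, mushroom, ramified, plus transitional and
# atypical): the class-conditional geometry ranges below realise the
# taxonomy's contrasts — thin has head close to neck calibre, mushroom has a
# clearly bulbous head on a thin neck, stubby is neckless with length close
# to its base, wide is neckless and laterally dominant, ramified carries two
# heads on one stalk. All ranges are configurable.

#' Class-conditional spine geometry ranges
#'
#' Each entry gives uniform sampling ranges (um) for the generator. The
#' defaults keep the classes well separated relative to the classifier's
#' ratio thresholds.
#'
#' @return A named list of per-class geometry ranges.
#' @export
spine_geometry_defaults <- function() {
  list(
    thin = list(neck_length = c(0.70, 0.90), neck_diameter = c(0.20, 0.24),
                head_ratio = c(1.12, 1.28)),
    stubby = list(lateral_semi = c(0.20, 0.26), length_ratio = c(0.78, 0.86)),
    wide = list(height = c(0.26, 0.32), lateral_ratio = c(1.8, 2.6)),
    mushroom = list(neck_length = c(0.45, 0.65), neck_diameter = c(0.16, 0.22),
                    head_diameter = c(0.55, 0.70)),
    ramified = list(stalk_length = c(0.35, 0.50), stalk_diameter = c(0.22, 0.28),
                    branch_length = c(0.35, 0.45), branch_angle = c(38, 50),
                    head_diameter = c(0.40, 0.46)),
    transitional = list(neck_length = c(0.35, 0.50), neck_diameter = c(0.20, 0.24),
                        head_ratio = c(1.45, 1.55)),
    atypical = list(neck_length = c(0.30, 0.40), neck_diameter = c(0.18, 0.22),
                    head_diameter = c(0.35, 0.45)),
    spinule = list(length = c(0.25, 0.35), diameter = 0.16)
  )
}

ru <- function(rng) if (length(rng) == 2L) runif(1, rng[1], rng[2]) else rng

# sample one spine's geometry given its class
sample_spine_geometry <- function(class_label, geom = spine_geometry_defaults()) {
  g <- geom[[class_label]]
  switch(class_label,
    thin = {
      nd <- ru(g$neck_diameter)
      hd <- nd * ru(g$head_ratio)
      nl <- ru(g$neck_length)
      list(neck_length = nl, neck_diameter = nd, head_diameter = hd,
           n_heads = 1L, length = nl + hd)
    },
    stubby = {
      a <- ru(g$lateral_semi)
      len <- 2 * a * ru(g$length_ratio)     # length just below the base width
      list(neck_length = 0, neck_diameter = 2 * a, head_diameter = 2 * a,
           n_heads = 1L, length = len, lateral_semi = a, height = len)
    },
    wide = {
      h <- ru(g$height)
      a <- h * ru(g$lateral_ratio) / 2      # laterally dominant bump
      list(neck_length = 0, neck_diameter = 2 * a, head_diameter = 2 * a,
           n_heads = 1L, length = h, lateral_semi = a, height = h)
    },
    mushroom = {
      nl <- ru(g$neck_length)
      nd <- ru(g$neck_diameter)
      hd <- ru(g$head_diameter)
      list(neck_length = nl, neck_diameter = nd, head_diameter = hd,
           n_heads = 1L, length = nl + hd)
    },
    ramified = {
      sl <- ru(g$stalk_length)
      sd_ <- ru(g$stalk_diameter)
      bl <- ru(g$branch_length)
      ba <- ru(g$branch_angle)
      hd <- ru(g$head_diameter)
      list(neck_length = sl, neck_diameter = sd_, head_diameter = hd,
           n_heads = 2L, length = sl + bl + hd,
           branch_length = bl, branch_angle = ba)
    },
    transitional = {
      nd <- ru(g$neck_diameter)
      hd <- nd * ru(g$head_ratio)
      nl <- ru(g$neck_length)
      list(neck_length = nl, neck_diameter = nd, head_diameter = hd,
           n_heads = 1L, length = nl + hd)
    },
    atypical = {
      nl <- ru(g$neck_length)
      nd <- ru(g$neck_diameter)
      hd <- ru(g$head_diameter)
      # serial double bulb: neck-bulb-neck-bulb along one axis
      list(neck_length = nl, neck_diameter = nd, head_diameter = hd,
           n_heads = 1L, length = 2 * nl + 2 * hd, serial = TRUE)
    },
    stop("unknown spine class: ", class_label)
  )
}

# arclength-parametrised dendritic path(s) of a morphology: list of tibbles
# with x, y, z, radius, arclen
dendritic_paths <- function(m) {
  pidx <- match(m$parent, m$id)
  kids <- split(seq_len(nrow(m)), pidx[seq_len(nrow(m))])
  dend <- function(v) m$type[v] %in% c(3L, 4L)
  starts <- which(dend(seq_len(nrow(m))) &
                    (m$parent == -1L | !dend(pidx[seq_len(nrow(m))])))
  paths <- list()
  walk <- function(start) {
    seg <- start
    v <- start
    repeat {
      ch <- kids[[as.character(v)]]
      ch <- ch[dend(ch)]
      if (length(ch) == 0L) break
      if (length(ch) > 1L) {
        for (c2 in ch[-1]) walk(c2)
        ch <- ch[1]
      }
      seg <- c(seg, ch)
      v <- ch
    }
    xyz <- as.matrix(m[seg, c("x", "y", "z")])
    d <- c(0, sqrt(rowSums(diff(xyz)^2)))
    paths[[length(paths) + 1L]] <<- tibble(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = m$radius[seg], arclen = cumsum(d)
    )
  }
  for (s in starts) walk(s)
  paths
}

# point, tangent and radius at arclength s along a path tibble
path_at <- function(path, s) {
  s <- clamp(s, 0, max(path$arclen))
  i <- findInterval(s, path$arclen, rightmost.closed = TRUE)
  i <- clamp(i, 1, nrow(path) - 1)
  t0 <- path$arclen[i]
  t1 <- path$arclen[i + 1]
  f <- if (t1 > t0) (s - t0) / (t1 - t0) else 0
  p0 <- c(path$x[i], path$y[i], path$z[i])
  p1 <- c(path$x[i + 1], path$y[i + 1], path$z[i + 1])
  list(point = p0 + f * (p1 - p0),
       tangent = unit(p1 - p0),
       radius = path$radius[i] + f * (path$radius[i + 1] - path$radius[i]))
}

#' Decorate a morphology with ground-truth spines
#'
#' Places spines along the dendritic arclength by a point process — a
#' homogeneous Poisson process when `grouping = 0`, a Neyman–Scott clustered
#' process (parents plus offspring within a 1 um window) for `grouping > 0` —
#' then applies a steric-exclusion rule (no two spines within
#' `min_separation` um of arclength AND less than 90 degrees apart in
#' azimuth, since spines are solid bodies). Each spine draws its class from
#' `class_mix` and its geometry from the class-conditional ranges; spinules
#' are added to a fraction of mushroom and ramified heads. Deterministic for
#' a fixed seed.
#'
#' @param morphology a [neuron_morphology()].
#' @param density_per_um expected spines per um of dendrite (>= 0).
#' @param class_mix named probability vector over spine classes; must sum
#'   to 1.
#' @param grouping clustering coefficient in `[0, 1)`; 0 = homogeneous
#'   Poisson.
#' @param seed RNG seed.
#' @param spinule_fraction fraction of mushroom/ramified spines given a
#'   spinule.
#' @param n_spines optional exact spine count, overriding the Poisson draw
#'   (used by fixtures that pin the count).
#' @param min_separation steric-exclusion arclength window, um.
#' @param geometry per-class geometry ranges, see [spine_geometry_defaults()].
#' @return A `phantom_truth` object: list with `morphology`, `spines`
#'   (tibble: class, geometry, attachment coordinates, direction, azimuth,
#'   arclength), `density_per_um` (realised), `decorated_length`, `seed`.
#' @export
decorate_with_spines <- function(morphology, density_per_um,
                                 class_mix = c(thin = 0.25, stubby = 0.20,
                                               wide = 0.15, mushroom = 0.30,
                                               ramified = 0.10),
                                 grouping = 0, seed = 1L,
                                 spinule_fraction = 0.15, n_spines = NULL,
                                 min_separation = 0.7,
                                 geometry = spine_geometry_defaults()) {
  stopifnot(inherits(morphology, "neuron_morphology"), density_per_um >= 0)
  if (abs(sum(class_mix) - 1) > 1e-6 || any(class_mix < 0) ||
      is.null(names(class_mix)) ||
      !all(names(class_mix) %in% names(spine_geometry_defaults()))) {
    stop("class_mix must be a named nonnegative vector over known classes summing to 1")
  }
  paths <- dendritic_paths(morphology)
  lens <- vapply(paths, function(p) max(p$arclen), 0)
  total_len <- sum(lens)

  with_seed(seed, {
    n <- if (!is.null(n_spines)) as.integer(n_spines) else rpois(1, density_per_um * total_len)
    if (n == 0L || total_len == 0) {
      n <- 0L
    }
    # global arclength positions (concatenated over paths)
    if (n == 0L) {
      # nothing to place
      spines <- empty_spine_table()
      pos <- azim <- numeric(0)
      classes <- character(0)
    } else if (grouping > 0) {
      k <- 1 + 3 * grouping            # mean cluster size
      n_parents <- max(1L, round(n / k))
      parents <- runif(n_parents, 0, total_len)
      pos <- parents[sample.int(n_parents, n, replace = TRUE)] +
        runif(n, -0.5, 0.5)
      pos <- clamp(pos, 0, total_len)
    } else {
      pos <- runif(n, 0, total_len)
    }
    if (n > 0L) {
      azim <- runif(n, 0, 360)
      # steric exclusion: resample offenders against already-accepted spines
      ord <- order(pos)
      pos <- pos[ord]; azim <- azim[ord]
      acc_pos <- acc_az <- numeric(0)
      for (i in seq_len(n)) {
        p <- pos[i]; a <- azim[i]
        for (try in 1:60) {
          clash <- any(abs(acc_pos - p) < min_separation &
                         pmin(abs(acc_az - a), 360 - abs(acc_az - a)) < 90)
          if (!clash) break
          p <- runif(1, 0, total_len)
          a <- runif(1, 0, 360)
        }
        acc_pos <- c(acc_pos, p); acc_az <- c(acc_az, a)
      }
      pos <- acc_pos; azim <- acc_az
      classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    }
    cum <- cumsum(lens)
    if (n > 0L) spines <- purrr::map(seq_len(n), function(i) {
      path_i <- findInterval(pos[i], c(0, cum), rightmost.closed = TRUE)
      path_i <- clamp(path_i, 1, length(paths))
      local_s <- pos[i] - c(0, cum)[path_i]
      at <- path_at(paths[[path_i]], local_s)
      dir0 <- orthogonal_unit(at$tangent)
      dir <- unit(rotate_about(dir0, at$tangent, azim[i]))
      g <- sample_spine_geometry(classes[i], geometry)
      has_sp <- classes[i] %in% c("mushroom", "ramified") &&
        runif(1) < spinule_fraction
      sp_len <- if (has_sp) ru(geometry$spinule$length) else 0
      attach <- at$point + dir * at$radius
      tibble(
        spine_id = i, class_label = classes[i],
        neck_length = g$neck_length, neck_diameter = g$neck_diameter,
        head_diameter = g$head_diameter, n_heads = g$n_heads,
        length = g$length,
        has_spinule = has_sp, spinule_length = sp_len,
        position_arclen = pos[i], azimuth = azim[i],
        attach_x = attach[1], attach_y = attach[2], attach_z = attach[3],
        dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
        tan_x = at$tangent[1], tan_y = at$tangent[2], tan_z = at$tangent[3],
        shaft_radius = at$radius,
        geom = list(g)
      )
    }) %>% bind_rows()
    new_phantom_truth(morphology, spines,
                      if (total_len > 0) n / total_len else 0, total_len, seed)
  })
}

empty_spine_table <- function() {
  tibble(
    spine_id = integer(), class_label = character(), neck_length = numeric(),
    neck_diameter = numeric(), head_diameter = numeric(), n_heads = integer(),
    length = numeric(), has_spinule = logical(), spinule_length = numeric(),
    position_arclen = numeric(), azimuth = numeric(),
    attach_x = numeric(), attach_y = numeric(), attach_z = numeric(),
    dir_x = numeric(), dir_y = numeric(), dir_z = numeric(),
    tan_x = numeric(), tan_y = numeric(), tan_z = numeric(),
    shaft_radius = numeric(), geom = list()
  )
}

new_phantom_truth <- function(morphology, spines, density, length_um, seed) {
  structure(list(morphology = morphology, spines = spines,
                 density_per_um = density, decorated_length = length_um,
                 seed = seed),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d spines on %.1f um of dendrite (%.3f /um)\n",
              nrow(x$spines), x$decorated_length, x$density_per_um))
  if (nrow(x$spines)) print(count(x$spines, .data$class_label))
  invisible(x)
}
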