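# Rule-based spine taxonomy. The four measured feature groups (neck
# presence/length/diameter, protrusion count, head diameter, head shape)
# drive a first-match rule table over thin / stubby / wide / mushroom /
# ramified, with transitional assigned near class boundaries and atypical as
# the residual class. All thresholds live in one editable rule table.

#' Spine classification rule table
#'
#' Thresholds of the classifier. The taxonomy itself has no published
#' numbers (the original classification was by expert visual inspection), so
#' these defaults encode the standard quantitative contrasts: a neck exists
#' when the head is at least `neck_ratio` wider than the neck; a mushroom
#' head is at least `mushroom_ratio` times its neck; a thin spine is at least
#' `thin_elongation` times longer than its neck calibre with a modest head; a
#' stubby spine is neckless with length at most its base width; a wide spine
#' is neckless with lateral extent at least `wide_ratio` times its length
#' (lateral dominance also guards the stubby rule, which would otherwise
#' swallow wide spines); measurements within `transitional_band` (fractional)
#' of a deciding boundary are transitional.
#'
#' @param neck_ratio head/neck ratio at which a neck is present.
#' @param mushroom_ratio head/neck ratio of the mushroom rule.
#' @param thin_elongation length/neck-diameter ratio of the thin rule.
#' @param stubby_max_length_base maximal length/base ratio for stubby.
#' @param wide_ratio minimal base/length ratio for wide.
#' @param transitional_band fractional half-width of the boundary band.
#' @param spinule_max_length,spinule_max_diameter spinule caps, um.
#' @param min_protrusion_voxels floor on a countable distal compartment.
#' @return A `spine_rules` list.
#' @export
spine_rules <- function(neck_ratio = 1.2, mushroom_ratio = 1.5,
                        thin_elongation = 3, stubby_max_length_base = 1,
                        wide_ratio = 1.5, transitional_band = 0.10,
                        spinule_max_length = 0.4, spinule_max_diameter = 0.2,
                        min_protrusion_voxels = 12) {
  structure(list(neck_ratio = neck_ratio, mushroom_ratio = mushroom_ratio,
                 thin_elongation = thin_elongation,
                 stubby_max_length_base = stubby_max_length_base,
                 wide_ratio = wide_ratio, transitional_band = transitional_band,
                 spinule_max_length = spinule_max_length,
                 spinule_max_diameter = spinule_max_diameter,
                 min_protrusion_voxels = min_protrusion_voxels),
            class = "spine_rules")
}

#' Classify one spine from its features
#'
#' Pure function of features and the rule table; always returns exactly one
#' label. Priority: ramified (>= 2 protrusions), then mushroom, thin (necked
#' rules), then stubby, wide (neckless rules); measurements within the
#' transitional band of a deciding boundary give `transitional`; anything
#' left is `atypical`.
#'
#' @param features a one-row tibble from [measure_spine()] (or a list with
#'   the same fields).
#' @param rules a [spine_rules()].
#' @return A single class label string.
#' @export
classify_spine <- function(features, rules = spine_rules()) {
  f <- as.list(features)
  band <- function(v, thr) is.finite(v) && abs(v - thr) <= rules$transitional_band * thr
  if (f$n_protrusions >= 2L) return("ramified")
  hn <- f$head_diameter / f$neck_diameter
  if (isTRUE(f$neck_present)) {
    if (band(hn, rules$mushroom_ratio)) return("transitional")
    if (hn >= rules$mushroom_ratio) return("mushroom")
    elong <- f$protrusion_length / f$neck_diameter
    if (band(elong, rules$thin_elongation)) return("transitional")
    if (elong >= rules$thin_elongation) return("thin")
    return("atypical")
  }
  lb <- f$protrusion_length / f$base_diameter
  bl <- f$base_diameter / f$protrusion_length
  if (band(bl, rules$wide_ratio)) return("transitional")
  if (bl >= rules$wide_ratio) return("wide")
  if (band(lb, rules$stubby_max_length_base)) return("transitional")
  if (lb <= rules$stubby_max_length_base) return("stubby")
  # filopodial thin: long slender protrusion whose head never clears the
  # neck-detection ratio still belongs to the thin class (slenderness on the
  # neck calibre, as in the necked thin rule)
  elong <- f$protrusion_length / f$neck_diameter
  if (band(elong, rules$thin_elongation)) return("transitional")
  if (elong >= rules$thin_elongation) return("thin")
  "atypical"
}

#' Detect, measure and classify all spines in a volume
#'
#' Batch driver: extracts the shaft axis, segments protrusion candidates,
#' measures each and assigns a class. Returns a tidy spine table.
#'
#' @param volume a [binary_volume()] (typically from [reconstruct_spines()]).
#' @param axis optional precomputed [extract_shaft_axis()] result.
#' @param rules a [spine_rules()].
#' @return A `spine_table` tibble: one row per spine with attachment
#'   coordinates (um), arclength position, features, class and spinule flag.
#' @export
classify_spines <- function(volume, axis = NULL, rules = spine_rules()) {
  stopifnot(inherits(volume, "binary_volume"))
  if (is.null(axis) && !any(volume$mask)) {
    # nothing reconstructed: an empty spine table, not an error
    cands <- list()
    axis_len <- 0
  } else {
    if (is.null(axis)) axis <- extract_shaft_axis(volume)
    cands <- segment_spines(volume, axis)
    axis_len <- max(axis$arclen)
  }
  margin <- attr(cands, "margin") %||% 0
  d <- dim(volume$mask)
  rows <- purrr::map(seq_along(cands), function(i) {
    cand <- cands[[i]]
    sub <- array(FALSE, dim = d)
    sub[cand$voxels] <- TRUE
    feats <- measure_spine(sub, cand$attachment_index, volume$spacing, rules,
                           heights = cand$heights, outward = cand$outward,
                           axis_point = cand$axis_point)
    label <- classify_spine(feats, rules)
    dplyr::bind_cols(
      tibble(spine_id = i,
             x = cand$attachment["x"], y = cand$attachment["y"],
             z = cand$attachment["z"],
             branch_arclen_um = cand$branch_arclen,
             class = label,
             contact_ambiguous = cand$contact_ambiguous),
      feats
    )
  })
  out <- if (length(rows)) bind_rows(rows) else tibble(
    spine_id = integer(), x = numeric(), y = numeric(), z = numeric(),
    branch_arclen_um = numeric(), class = character(),
    contact_ambiguous = logical(), neck_present = logical(),
    neck_length = numeric(), neck_diameter = numeric(),
    head_diameter = numeric(), base_diameter = numeric(),
    n_protrusions = integer(), head_shape = numeric(),
    protrusion_length = numeric(), spinule_count = integer()
  )
  out$has_spinule <- out$spinule_count >= 1L
  class(out) <- c("spine_table", class(out))
  attr(out, "axis_length_um") <- axis_len
  out
}

#' Spine density along the dendrite
#'
#' @param records a `spine_table` (or any data frame with one row per spine).
#' @param decorated_length dendritic length carrying the spines, um (> 0);
#'   defaults to the shaft-axis length recorded by [classify_spines()].
#' @param bins upper edges of the qualitative density bands, spines/um.
#' @return A list: `density_per_um`, `band`, `n_spines`, `length_um`,
#'   `per_class` (tibble of per-class counts and densities).
#' @export
spine_density <- function(records, decorated_length = NULL,
                          bins = c(sparse = 0.3, moderate = 1.0)) {
  decorated_length <- decorated_length %||% attr(records, "axis_length_um")
  if (is.null(decorated_length) || decorated_length <= 0) {
    stop("decorated_length must be positive")
  }
  n <- nrow(records)
  density <- n / decorated_length
  band <- if (density <= bins[["sparse"]]) "sparse"
          else if (density <= bins[["moderate"]]) "moderate"
          else "high"
  per_class <- if (n > 0 && "class" %in% names(records)) {
    records %>% count(.data$class, name = "n") %>%
      mutate(density_per_um = .data$n / decorated_length)
  } else {
    tibble(class = character(), n = integer(), density_per_um = numeric())
  }
  list(density_per_um = density, band = band, n_spines = n,
       length_um = decorated_length, per_class = per_class)
}

#' Match detected spines against ground truth
#'
#' Greedy nearest-neighbour matching on 3D attachment coordinates within
#' `max_dist` um: each truth spine is claimed by at most one detection.
#'
#' @param detected a `spine_table` (columns x, y, z, class).
#' @param truth a `phantom_truth` or its `spines` tibble
#'   (attach_x/y/z, class_label).
#' @param max_dist matching radius, um.
#' @return A list: `pairs` (tibble detected_id, truth_id, dist, class
#'   detected/truth), `recall`, `precision`, `mean_class_accuracy`,
#'   `confusion` (table).
#' @export
match_spines <- function(detected, truth, max_dist = 0.8) {
  tt <- if (inherits(truth, "phantom_truth")) truth$spines else truth
  nd <- nrow(detected)
  nt <- nrow(tt)
  if (nt == 0L || nd == 0L) {
    return(list(pairs = tibble(), recall = as.numeric(nt == 0),
                precision = as.numeric(nd == 0),
                mean_class_accuracy = NA_real_, confusion = table(NULL)))
  }
  D <- as.matrix(stats::dist(rbind(
    cbind(detected$x, detected$y, detected$z),
    cbind(tt$attach_x, tt$attach_y, tt$attach_z)
  )))[seq_len(nd), nd + seq_len(nt), drop = FALSE]
  pairs <- list()
  used_d <- logical(nd)
  used_t <- logical(nt)
  repeat {
    D2 <- D
    D2[used_d, ] <- Inf
    D2[, used_t] <- Inf
    mi <- which.min(D2)
    if (!length(mi) || !is.finite(D2[mi]) || D2[mi] > max_dist) break
    i <- (mi - 1) %% nd + 1
    j <- (mi - 1) %/% nd + 1
    used_d[i] <- TRUE
    used_t[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- tibble(
      detected_id = detected$spine_id[i], truth_id = tt$spine_id[j],
      dist = D[i, j], detected_class = detected$class[i],
      truth_class = tt$class_label[j]
    )
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(detected_id = integer(), truth_id = integer(), dist = numeric(),
           detected_class = character(), truth_class = character())
  recall <- nrow(pairs) / nt
  precision <- nrow(pairs) / nd
  if (nrow(pairs)) {
    per_class <- pairs %>% group_by(.data$truth_class) %>%
      summarise(acc = mean(.data$detected_class == .data$truth_class))
    # truth classes with no matched detection score 0
    missing <- setdiff(unique(tt$class_label), per_class$truth_class)
    accs <- c(per_class$acc, rep(0, length(missing)))
    mca <- mean(accs)
    confusion <- table(truth = pairs$truth_class, detected = pairs$detected_class)
  } else {
    mca <- 0
    confusion <- table(NULL)
  }
  list(pairs = pairs, recall = recall, precision = precision,
       mean_class_accuracy = mca, confusion = confusion)
}
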